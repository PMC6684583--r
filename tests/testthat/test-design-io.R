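test_that("the ten-plex design is valid and exposes the expected structure", {
  d <- tenplexDesign()
  expect_s4_class(d, "CoipDesign")
  expect_length(channelIds(d), 10L)
  expect_length(baitSamples(d), 4L)
  expect_length(nonIggSamples(d), 8L)
  cm <- controlMatching(d)
  expect_setequal(names(cm), c("agarose", "magnetic"))
  expect_identical(sampleChemistry(d, "Bait.Mix.magnetic"), "magnetic")
  expect_identical(iggChannel(d, "agarose"),
                   sampleChannel(d, cm[["agarose"]]))
})

test_that("design validation rejects malformed layouts with named errors", {
  # duplicate channel ids
  expect_error(CoipDesign(c("126", "126"), c("a", "b"), c("IgG", "x"),
                          c("agarose", "agarose"), c("igg_control", "bait")),
               "duplicate channel_id")
  # two IgG controls on one chemistry
  expect_error(CoipDesign(c("126", "127N", "127C"), c("a", "b", "c"),
                          c("IgG", "IgG2", "x"), rep("agarose", 3),
                          c("igg_control", "igg_control", "bait")),
               "igg_control channels for chemistry 'agarose'")
  # missing IgG control for a chemistry in use
  expect_error(CoipDesign(c("126", "127N"), c("a", "b"), c("IgG", "x"),
                          c("agarose", "magnetic"), c("igg_control", "bait")),
               "no igg_control channel for chemistry 'magnetic'")
  # unknown enum values
  expect_error(CoipDesign("126", "a", "IgG", "sepharose", "igg_control"),
               "unknown chemistry")
  expect_error(CoipDesign("126", "a", "IgG", "agarose", "input"),
               "unknown role")
  # IgG-control channel must carry an IgG-like antibody label
  expect_error(CoipDesign("126", "a", "C-10", "agarose", "igg_control"),
               "non-IgG antibody")
  # minimal three-channel design is legal
  expect_s4_class(design3(), "CoipDesign")
})

test_that("design YAML round-trips and readDesign validates", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeDesign(tenplexDesign(), tmp)
  d2 <- readDesign(tmp)
  expect_identical(designTable(d2), designTable(tenplexDesign()))

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("channels:", "  - channel_id: '126'", "    sample_name: a"), bad)
  expect_error(readDesign(bad), "missing field")
})

test_that("protein-group TSV parsing maps channels, flags and errors", {
  d <- design3()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(protein_id = sprintf("P%d", 1:5),
                    gene_symbol = letters[1:5],
                    n_peptides = c(3L, 1L, 5L, 2L, 4L),
                    is_contaminant = c("", "", "+", "", ""),
                    is_decoy = c("", "", "", "+", ""),
                    check.names = FALSE)
  sig <- matrix(seq_len(15) * 10, 5, 3,
                dimnames = list(NULL, paste("signal", channelIds(d))))
  write.table(cbind(tab, sig), tmp, sep = "\t", quote = FALSE, row.names = FALSE)

  x <- readProteinGroups(tmp, d)
  expect_s4_class(x, "CoipExperiment")
  expect_identical(dim(x), c(5L, 3L))
  expect_identical(unname(assay(x, "signal")[, "127N"]), seq(60, 100, 10))
  expect_identical(rowData(x)$is_decoy, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(rowData(x)$is_contaminant, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  # MaxQuant-style reporter columns are recognized through the alias map
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  mq <- data.frame(`Majority protein IDs` = c("Q1", "Q2"),
                   Peptides = c(4L, 2L),
                   `Reporter intensity corrected 1` = c(1, 2),
                   `Reporter intensity corrected 2` = c(3, 4),
                   `Reporter intensity corrected 3` = c(5, 6),
                   check.names = FALSE)
  write.table(mq, tmp2, sep = "\t", quote = FALSE, row.names = FALSE)
  x2 <- readProteinGroups(tmp2, d)
  expect_identical(unname(assay(x2)[, "127C"]), c(5, 6))

  # missing column and bad signal raise informative errors
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tmp3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readProteinGroups(tmp3, d), "no signal column")
  tmp4 <- withr::local_tempfile(fileext = ".tsv")
  sig2 <- sig; sig2[2, 1] <- -5
  write.table(cbind(tab, sig2), tmp4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readProteinGroups(tmp4, d), "line 3.*non-negative")
})

test_that("simulated tables round-trip through the writers and readers", {
  sim <- simulateCoip(smallConfig(3), design3(), psms = TRUE)
  dir <- withr::local_tempdir()
  paths <- writeSimulatedTables(sim, dir)
  d <- readDesign(paths[["design"]])
  expect_identical(designTable(d), designTable(design3()))
  x <- readProteinGroups(paths[["protein_groups"]], d)
  expect_equal(assay(x, "signal"), assay(sim$experiment, "signal"),
               tolerance = 1e-12)
  expect_identical(rowData(x)$n_peptides, rowData(sim$experiment)$n_peptides)
  psms <- readPsmTable(paths[["psms"]], d)
  expect_equal(nrow(psms), nrow(sim$psms))
  agg <- proteinSignalFromPsms(psms, d)
  expect_equal(assay(agg)[rownames(x), ], assay(x, "signal"), tolerance = 1e-9)
})

test_that("row order of the input table does not change downstream results", {
  sim <- simulateCoip(smallConfig(4), design3(), psms = FALSE)
  dir <- withr::local_tempdir()
  paths <- writeSimulatedTables(sim, dir)
  tab <- read.delim(paths[["protein_groups"]], check.names = FALSE)
  perm <- withr::with_seed(99, sample(nrow(tab)))
  shuf <- file.path(dir, "shuffled.tsv")
  write.table(tab[perm, ], shuf, sep = "\t", quote = FALSE, row.names = FALSE)
  run1 <- function(path) {
    et <- enrichmentRatios(relativeAbundance(readProteinGroups(path, design3())))
    assembleInteractome(et, deriveCutoffs(et, minValues = 10L))
  }
  r1 <- run1(paths[["protein_groups"]])
  r2 <- run1(shuf)
  expect_setequal(interactome(r1), interactome(r2))
  expect_setequal(interactomeBackground(r1), interactomeBackground(r2))
  for (s in names(enrichedSets(r1)))
    expect_setequal(enrichedSets(r1)[[s]], enrichedSets(r2)[[s]])
})

test_that("results writer emits TSV + JSON that reload to the same sets", {
  sim <- simulateCoip(smallConfig(5), psms = FALSE)
  et <- enrichmentRatios(relativeAbundance(sim$experiment))
  res <- assembleInteractome(et, deriveCutoffs(et))
  ov <- pairwiseOverlapMatrix(res)
  dir <- withr::local_tempdir()
  paths <- writeResults(res, et, file.path(dir, "out"), overlaps = ov)
  expect_true(all(file.exists(paths)))
  back <- readResults(paths[["json"]])
  expect_setequal(back$interactome, interactome(res))
  expect_setequal(back$background, interactomeBackground(res))
  for (s in names(enrichedSets(res)))
    expect_setequal(back$enriched_sets[[s]], enrichedSets(res)[[s]])
  # numeric fields reload at full precision
  expect_equal(back$cutoffs$theta, cutoffTheta(res@cutoffs), tolerance = 1e-12)
  expect_equal(back$pseudocount, pseudocountUsed(et), tolerance = 1e-12)
  expect_equal(back$overlaps$p, ov$p, tolerance = 1e-12)
  tsv <- read.delim(paths[["tsv"]], check.names = FALSE)
  expect_identical(sum(tsv$in_background), length(interactomeBackground(res)))
})

test_that("an empty interactome still writes valid, reloadable JSON", {
  sim <- simulateCoip(smallConfig(6), psms = FALSE)
  et <- enrichmentRatios(relativeAbundance(sim$experiment))
  cut <- new("CutoffSet", theta = c(agarose = 1e9, magnetic = 1e9),
             q = 0.95, minPeptides = 3L, scope = "chemistry")
  res <- assembleInteractome(et, cut)
  expect_length(interactome(res), 0L)
  dir <- withr::local_tempdir()
  paths <- writeResults(res, et, file.path(dir, "empty"))
  back <- readResults(paths[["json"]])
  expect_length(back$interactome, 0L)
  expect_identical(back$interactome_size, 0L)
})
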