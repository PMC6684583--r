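test_that("relative abundance normalizes every channel to unit sum", {
  # a single protein owns the whole channel
  s1 <- matrix(c(5, 7, 9), 1, 3,
               dimnames = list("P1", channelIds(design3())))
  a1 <- assay(relativeAbundance(experiment3(s1)), "relabund")
  expect_equal(unname(a1[1, ]), c(1, 1, 1))
  # 3:1 split
  s2 <- matrix(c(3, 3, 3, 1, 1, 1), 2, 3, byrow = FALSE,
               dimnames = list(c("P1", "P2"), channelIds(design3())))
  s2[] <- c(3, 1, 3, 1, 3, 1)
  a2 <- assay(relativeAbundance(experiment3(s2)), "relabund")
  expect_equal(unname(a2[, 1]), c(0.75, 0.25))
  # random matrices: all columns sum to one
  for (s in 1:5) {
    m <- withr::with_seed(s, matrix(rlnorm(300, 8, 2), 100, 3))
    dimnames(m) <- list(sprintf("P%03d", 1:100), channelIds(design3()))
    a <- assay(relativeAbundance(experiment3(m)), "relabund")
    expect_true(all(abs(colSums(a) - 1) <= 1e-9))
  }
  # contaminant/decoy rows are excluded before normalization
  x <- CoipExperiment(s2, design3(), nPeptides = c(3L, 3L),
                      isContaminant = c(FALSE, TRUE))
  a3 <- assay(relativeAbundance(x), "relabund")
  expect_identical(rownames(a3), "P1")
  expect_equal(unname(a3[1, ]), c(1, 1, 1))
  # an all-zero channel is a named degenerate-channel error
  s0 <- s2; s0[, 2] <- 0
  expect_error(relativeAbundance(experiment3(s0)), "127N")
})

test_that("enrichment ratios divide by the chemistry-matched IgG abundance", {
  d <- design3()
  sig <- matrix(c(10, 10, 20, 10, 10, 10), 2, 3,
                dimnames = list(c("P1", "P2"), channelIds(d)))
  # P1: IgG share 0.5, bait share 2/3 -> E = 4/3; equal shares -> E = 1
  et <- enrichmentRatios(relativeAbundance(experiment3(sig)))
  expect_equal(enrichmentMatrix(et)["P1", "Bait.ag"], (2/3) / 0.5)
  expect_equal(enrichmentMatrix(et)["P1", "Unrel.ag"], 1.0)
  expect_equal(enrichmentMatrix(et)["P2", "Bait.ag"], (1/3) / 0.5)
  # a_ip = 0.002, a_igg = 0.001 -> E = 2 (4-protein fixture)
  sig2 <- rbind(P1 = c(1, 2, 1), P2 = c(499, 498, 499),
                P3 = c(300, 300, 300), P4 = c(200, 200, 200))
  colnames(sig2) <- channelIds(d)
  et2 <- enrichmentRatios(relativeAbundance(experiment3(sig2)))
  expect_equal(enrichmentMatrix(et2)["P1", "Bait.ag"], 2.0)
})

test_that("pseudocount policies keep ratios finite, as hand-computed", {
  d <- design3()
  # P1 absent from the IgG channel; shares in IgG: 0, .5, .3, .2
  sig <- rbind(P1 = c(0, 120, 50), P2 = c(500, 400, 450),
               P3 = c(300, 280, 300), P4 = c(200, 200, 200))
  colnames(sig) <- channelIds(d)
  x <- relativeAbundance(experiment3(sig))
  et <- enrichmentRatios(x)  # halfmin: eps = 0.2 / 2 = 0.1
  expect_equal(unname(pseudocountUsed(et)[["126"]]), 0.1)
  a_bait <- 120 / 1000
  expect_equal(enrichmentMatrix(et)["P1", "Bait.ag"], a_bait / 0.1)
  expect_true(all(is.finite(enrichmentMatrix(et))))
  # fixed policy
  etf <- enrichmentRatios(x, pseudocount = "fixed", eps = 0.05)
  expect_equal(enrichmentMatrix(etf)["P1", "Bait.ag"], a_bait / 0.05)
  expect_error(enrichmentRatios(x, pseudocount = "fixed"), "eps")
  # drop policy marks the ratio NA and keeps others
  etd <- enrichmentRatios(x, pseudocount = "drop")
  expect_true(is.na(enrichmentMatrix(etd)["P1", "Bait.ag"]))
  expect_false(anyNA(enrichmentMatrix(etd)[c("P2", "P3", "P4"), ]))
})

test_that("cutoffs are the type-7 quantile of pooled ratios", {
  d <- design3()
  mk_et <- function(vals) {
    # two pooled columns of equal values; peptide filter trivially passed
    n <- length(vals)
    ratios <- cbind(Bait.ag = vals, Unrel.ag = vals)
    rownames(ratios) <- sprintf("P%03d", seq_len(n))
    new("EnrichmentTable", ratios = ratios,
        nPeptides = structure(rep(5L, n), names = rownames(ratios)),
        pseudocount = c("126" = 1e-4), design = d)
  }
  expect_equal(unname(cutoffTheta(deriveCutoffs(mk_et(rep(2, 20))))["agarose"]), 2)
  # 1..20 at q = 0.95 with linear interpolation: 19.05
  th <- cutoffTheta(deriveCutoffs(mk_et(1:20)))[["agarose"]]
  expect_equal(th, quantile(c(1:20, 1:20), 0.95, type = 7, names = FALSE))
  th1 <- cutoffTheta(deriveCutoffs(mk_et(1:20), scope = "sample"))
  expect_equal(unname(th1[["Bait.ag"]]), 19.05)
  expect_error(deriveCutoffs(mk_et(rep(2, 5)), scope = "sample"),
               "insufficient data")
  # peptide filter is applied before pooling by default
  et <- mk_et(1:20)
  et@nPeptides[sprintf("P%03d", 11:20)] <- 1L
  th2 <- cutoffTheta(deriveCutoffs(et, scope = "sample",
                                   minValues = 10L))[["Bait.ag"]]
  expect_equal(th2, quantile(1:10, 0.95, type = 7, names = FALSE))
  th3 <- cutoffTheta(deriveCutoffs(et, scope = "sample",
                                   filterFirst = FALSE))[["Bait.ag"]]
  expect_equal(th3, 19.05)
})

test_that("enriched sets honor the peptide filter and strictness", {
  d <- design3()
  ratios <- cbind(Bait.ag = c(1.5, 1.5, 1.4, 5.0), Unrel.ag = c(1, 1, 1, 1))
  rownames(ratios) <- c("A", "B", "C", "D")
  et <- new("EnrichmentTable", ratios = ratios,
            nPeptides = c(A = 3L, B = 2L, C = 3L, D = 7L),
            pseudocount = c("126" = 1e-4), design = d)
  cut <- new("CutoffSet", theta = c(agarose = 1.4), q = 0.95,
             minPeptides = 3L, scope = "chemistry")
  # E = 1.5 with 3 peptides passes; 2 peptides fails; E exactly at the
  # cutoff is excluded under the strict ">" rule but included under ">="
  expect_setequal(enrichedSet(et, cut, "Bait.ag"), c("A", "D"))
  expect_setequal(enrichedSet(et, cut, "Bait.ag", strict = FALSE),
                  c("A", "C", "D"))
  expect_error(enrichedSet(et, cut, "nope"), "unknown sample")
})

test_that("assembly takes unions over baits and all non-IgG samples", {
  d <- tenplexDesign()
  samples <- nonIggSamples(d)
  prot <- c("A", "B", "C", "D", "E")
  ratios <- matrix(1, 5, 8, dimnames = list(prot, samples))
  ratios["A", "Bait.Mix.agarose"] <- 10
  ratios["B", c("Bait.Mix.agarose", "Bait.C10.agarose")] <- 10
  ratios["C", "Bait.C10.agarose"] <- 10
  ratios["D", "Unrel1.agarose"] <- 10
  et <- new("EnrichmentTable", ratios = ratios,
            nPeptides = structure(rep(4L, 5), names = prot),
            pseudocount = c("126" = 1e-4, "129N" = 1e-4), design = d)
  cut <- new("CutoffSet", theta = c(agarose = 2, magnetic = 2), q = 0.95,
             minPeptides = 3L, scope = "chemistry")
  res <- assembleInteractome(et, cut)
  expect_setequal(interactome(res), c("A", "B", "C"))
  expect_setequal(interactomeBackground(res), c("A", "B", "C", "D"))
  expect_true(all(interactome(res) %in% interactomeBackground(res)))
})

test_that("raising the cutoff or the peptide filter shrinks enriched sets", {
  for (s in 1:10) {
    sim <- simulateCoip(smallConfig(s), psms = FALSE)
    et <- enrichmentRatios(relativeAbundance(sim$experiment))
    cut <- deriveCutoffs(et)
    res <- assembleInteractome(et, cut)
    expect_true(all(interactome(res) %in% interactomeBackground(res)))
    up <- cut; up@theta <- cut@theta * 1.5
    res_up <- assembleInteractome(et, up)
    pep <- cut; pep@minPeptides <- cut@minPeptides + 2L
    res_pep <- assembleInteractome(et, pep)
    for (smp in names(enrichedSets(res))) {
      expect_true(all(enrichedSets(res_up)[[smp]] %in% enrichedSets(res)[[smp]]))
      expect_true(all(enrichedSets(res_pep)[[smp]] %in% enrichedSets(res)[[smp]]))
    }
  }
})

test_that("per-channel rescaling leaves ratios and sets unchanged", {
  sim <- simulateCoip(smallConfig(21), design3(), psms = FALSE)
  x <- sim$experiment
  et <- enrichmentRatios(relativeAbundance(x))
  sig <- assay(x, "signal")
  scaled <- sweep(sig, 2L, c(7, 0.3, 19), "*")
  x2 <- CoipExperiment(scaled, coipDesign(x),
                       nPeptides = rowData(x)$n_peptides,
                       isContaminant = rowData(x)$is_contaminant,
                       isDecoy = rowData(x)$is_decoy)
  et2 <- enrichmentRatios(relativeAbundance(x2))
  expect_equal(enrichmentMatrix(et2), enrichmentMatrix(et), tolerance = 1e-12)
  r1 <- assembleInteractome(et, deriveCutoffs(et))
  r2 <- assembleInteractome(et2, deriveCutoffs(et2))
  expect_setequal(interactome(r1), interactome(r2))
})

test_that("the full pipeline is deterministic for identical inputs", {
  r1 <- runPipeline(simConfig = smallConfig(31))
  r2 <- runPipeline(simConfig = smallConfig(31))
  expect_identical(enrichmentMatrix(r1$enrichment), enrichmentMatrix(r2$enrichment))
  expect_identical(interactome(r1$result), interactome(r2$result))
  expect_identical(r1$overlaps, r2$overlaps)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
})
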