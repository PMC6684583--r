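# 32-bit FNV-1a over a string; tiny stable hash for run manifests.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte; keep h a double (it exceeds int range)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403:
    # h*2^24 mod 2^32 only keeps the low 8 bits of h
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.log_line <- function(msg, logfile = NULL, verbose = TRUE) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  if (verbose) message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the full interactome-scoring pipeline
#'
#' Orchestrates one reproducible run: (simulate or load) -> mixing-factor QC
#' -> PSM aggregation -> relative abundance -> IgG-normalized ratios ->
#' cutoff derivation -> enriched sets -> interactome/background assembly ->
#' pairwise overlap statistics (-> recovery scoring when simulated). Exactly
#' one of \code{simConfig} or \code{proteinGroups} must be supplied. When
#' \code{outDir} is given, all artifacts are written there: enrichment TSV,
#' result JSON, overlap TSV, a plain-text report, a log, and a manifest JSON
#' (package version, seed, option hash) that fully determines the outputs.
#'
#' @param design A [CoipDesign-class], or a path to a design YAML.
#' @param simConfig A [SimulationConfig-class] to generate the inputs.
#' @param proteinGroups Path to a protein-group TSV, or a
#'   [CoipExperiment-class].
#' @param psms Optional PSM table (path or data.frame) for labeling/mixing QC
#'   and aggregation when starting from PSM level.
#' @param q,minPeptides,strict,pseudocount,eps,poolScope,filterFirst Scoring
#'   options, see [deriveCutoffs()], [enrichedSet()], [enrichmentRatios()].
#' @param reference Reference sample for [pairwiseOverlapMatrix()]; default
#'   the first agarose bait.
#' @param adjust Multiple-testing adjustment for the overlap matrix.
#' @param outDir Output directory (optional).
#' @param verbose Log progress to stderr.
#' @return A list with \code{experiment}, \code{enrichment}, \code{cutoffs},
#'   \code{result} ([InteractomeResult-class]), \code{overlaps},
#'   \code{mixing} (QC), \code{recovery} (when simulated), \code{manifest}.
#' @export
runPipeline <- function(design = tenplexDesign(), simConfig = NULL,
                        proteinGroups = NULL, psms = NULL,
                        q = 0.95, minPeptides = 3L, strict = TRUE,
                        pseudocount = "halfmin", eps = NULL,
                        poolScope = "chemistry", filterFirst = TRUE,
                        reference = NULL, adjust = "none",
                        outDir = NULL, verbose = FALSE) {
  if (is.character(design)) design <- readDesign(design)
  if (is.null(simConfig) == is.null(proteinGroups))
    stop("supply exactly one of 'simConfig' (simulation) or 'proteinGroups' (data)")
  logfile <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logfile <- file.path(outDir, "run.log")
    if (file.exists(logfile)) unlink(logfile)
  }
  say <- function(...) .log_line(sprintf(...), logfile, verbose)

  stage <- function(name, expr) {
    say("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  psm_tab <- NULL
  if (!is.null(simConfig)) {
    sim <- stage("simulate", simulateCoip(simConfig, design, psms = TRUE))
    experiment <- sim$experiment
    truth <- sim$truth
    psm_tab <- sim$psms
  } else {
    experiment <- stage("load", {
      if (is(proteinGroups, "CoipExperiment")) proteinGroups
      else readProteinGroups(proteinGroups, design)
    })
    if (!is.null(psms))
      psm_tab <- if (is.character(psms)) readPsmTable(psms, design) else psms
  }

  mixing <- NULL
  labeling <- NULL
  if (!is.null(psm_tab)) {
    labeling <- stage("labeling_qc", labelingEfficiency(psm_tab))
    mixing <- stage("mixing_qc", {
      pm <- peptideMatrix(psm_tab, design)
      mixingCorrectionFactors(pm)
    })
    if (is.null(simConfig)) {
      # data runs starting from PSMs: aggregate to protein level ourselves
      experiment <- stage("aggregate", proteinSignalFromPsms(psm_tab, design))
    }
  }

  experiment <- stage("relative_abundance", relativeAbundance(experiment))
  enrichment <- stage("ratios",
                      enrichmentRatios(experiment, pseudocount = pseudocount, eps = eps))
  cutoffs <- stage("cutoffs",
                   deriveCutoffs(enrichment, q = q, minPeptides = minPeptides,
                                 scope = poolScope, filterFirst = filterFirst))
  result <- stage("assemble", assembleInteractome(enrichment, cutoffs, strict = strict))
  overlaps <- stage("overlap",
                    pairwiseOverlapMatrix(result, reference = reference,
                                          adjust = adjust))
  recovery <- if (!is.null(truth))
    stage("recovery", scoreRecovery(result, truth, design)) else NULL

  opts <- list(q = q, minPeptides = as.integer(minPeptides), strict = strict,
               pseudocount = pseudocount, eps = eps, poolScope = poolScope,
               filterFirst = filterFirst, reference = reference, adjust = adjust,
               seed = if (!is.null(simConfig)) simConfig@seed else NULL,
               design = as.list(designTable(design)))
  optjson <- as.character(jsonlite::toJSON(opts, auto_unbox = TRUE, digits = NA,
                                           null = "null"))
  manifest <- list(package = "coipTMT",
                   version = as.character(utils::packageVersion("coipTMT")),
                   config_hash = .fnv1a(optjson),
                   options = opts)

  if (!is.null(outDir)) {
    say("writing artifacts to %s", outDir)
    writeResults(result, enrichment, file.path(outDir, "coip"), overlaps = overlaps)
    utils::write.table(overlaps, file.path(outDir, "overlaps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
               file.path(outDir, "manifest.json"))
    writeLines(.run_report(result, cutoffs, overlaps, recovery, mixing, labeling),
               file.path(outDir, "report.txt"))
  }
  say("done: interactome %d, background %d",
      length(interactome(result)), length(interactomeBackground(result)))
  list(experiment = experiment, enrichment = enrichment, cutoffs = cutoffs,
       result = result, overlaps = overlaps, mixing = mixing,
       labeling = labeling, recovery = recovery, truth = truth,
       manifest = manifest)
}

.run_report <- function(result, cutoffs, overlaps, recovery, mixing, labeling) {
  out <- c("Interactome scoring report", "==========================", "")
  out <- c(out, sprintf("cutoffs (top %.0f%%, >=%d peptides):",
                        100 * (1 - cutoffs@q), cutoffs@minPeptides),
           sprintf("  %s: %.4f", names(cutoffs@theta), cutoffs@theta), "")
  if (!is.null(labeling))
    out <- c(out, sprintf("labeling efficiency: %.3f (%s)", labeling$efficiency,
                          if (labeling$pass) "pass" else "FAIL"), "")
  if (!is.null(mixing))
    out <- c(out, "mixing factors:",
             sprintf("  %s: %.4f%s", names(mixing@factors), mixing@factors,
                     ifelse(mixing@withinBand, "", " [outside QC band]")), "")
  sizes <- vapply(enrichedSets(result), length, integer(1))
  out <- c(out, "enriched proteins per sample:",
           sprintf("  %s: %d", names(sizes), sizes), "",
           sprintf("interactome: %d proteins", length(interactome(result))),
           sprintf("background: %d proteins", length(interactomeBackground(result))), "",
           "pairwise overlap vs reference:",
           utils::capture.output(print(overlaps, row.names = FALSE)))
  if (!is.null(recovery))
    out <- c(out, "", sprintf("recovery: precision %.3f, recall %.3f, F1 %.3f",
                              recovery@precision, recovery@recall, recovery@f1))
  out
}
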