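#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

.CHEMISTRIES <- c("agarose", "magnetic")
.ROLES <- c("igg_control", "bait", "unrelated_control")

#' Experiment design for a multiplexed co-IP run
#'
#' A \code{CoipDesign} maps every isobaric labeling channel to an
#' immunoprecipitation sample: the antibody used, the bead chemistry
#' (protein-G agarose or epoxy magnetic), and the sample's role. Roles are
#' \code{"igg_control"} (nonspecific-IgG background IP), \code{"bait"}
#' (an IP against the protein of interest), or \code{"unrelated_control"}
#' (an IP against an unrelated protein, used to gauge specificity).
#'
#' Validity requires unique channel identifiers and sample names, exactly one
#' IgG control per bead chemistry present in the design, and an IgG-like
#' antibody label on every IgG-control channel. Each non-IgG sample is
#' normalized against the IgG control of its own chemistry.
#'
#' @slot channels A \code{DataFrame} with columns \code{channel_id},
#'   \code{sample_name}, \code{antibody}, \code{chemistry}, \code{role}.
#'
#' @seealso [CoipDesign()], [readDesign()], [tenplexDesign()]
#' @export
setClass("CoipDesign", representation(channels = "DataFrame"))

setValidity("CoipDesign", function(object) {
  ch <- object@channels
  need <- c("channel_id", "sample_name", "antibody", "chemistry", "role")
  miss <- setdiff(need, colnames(ch))
  if (length(miss))
    return(sprintf("missing design column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(ch) < 1L) return("design has no channels")
  if (anyDuplicated(ch$channel_id))
    return(sprintf("duplicate channel_id: %s",
                   paste(unique(ch$channel_id[duplicated(ch$channel_id)]), collapse = ", ")))
  if (anyDuplicated(ch$sample_name))
    return(sprintf("duplicate sample_name: %s",
                   paste(unique(ch$sample_name[duplicated(ch$sample_name)]), collapse = ", ")))
  bad <- setdiff(unique(ch$chemistry), .CHEMISTRIES)
  if (length(bad))
    return(sprintf("unknown chemistry value(s): %s (allowed: %s)",
                   paste(bad, collapse = ", "), paste(.CHEMISTRIES, collapse = ", ")))
  bad <- setdiff(unique(ch$role), .ROLES)
  if (length(bad))
    return(sprintf("unknown role value(s): %s (allowed: %s)",
                   paste(bad, collapse = ", "), paste(.ROLES, collapse = ", ")))
  igg <- ch[ch$role == "igg_control", , drop = FALSE]
  notigg <- !grepl("igg", igg$antibody, ignore.case = TRUE)
  if (any(notigg))
    return(sprintf("igg_control channel(s) %s carry non-IgG antibody label(s)",
                   paste(igg$channel_id[notigg], collapse = ", ")))
  for (chem in unique(ch$chemistry)) {
    n <- sum(igg$chemistry == chem)
    if (n == 0L)
      return(sprintf("no igg_control channel for chemistry '%s'", chem))
    if (n > 1L)
      return(sprintf("%d igg_control channels for chemistry '%s' (exactly one required)",
                     n, chem))
  }
  TRUE
})

#' Protein x channel reporter-signal container
#'
#' Extends \code{SummarizedExperiment}: rows are protein groups, columns are
#' the design's labeling channels, and the \code{"signal"} assay holds the
#' total reporter signal (reporter intensity times ion injection time, summed
#' over all spectra matching the protein group). Row metadata carries
#' \code{gene_symbol}, \code{n_peptides}, \code{is_contaminant} and
#' \code{is_decoy}; additional assays (e.g. \code{"relabund"}) are added by
#' downstream steps.
#'
#' @slot design The [CoipDesign-class] the columns follow.
#' @seealso [CoipExperiment()], [readProteinGroups()], [relativeAbundance()]
#' @export
setClass("CoipExperiment",
         contains = "SummarizedExperiment",
         representation(design = "CoipDesign"))

setValidity("CoipExperiment", function(object) {
  if (!"signal" %in% assayNames(object)) return("assay 'signal' is required")
  if (!identical(colnames(object), channelIds(object@design)))
    return("column names must equal the design's channel ids, in design order")
  rd <- rowData(object)
  need <- c("gene_symbol", "n_peptides", "is_contaminant", "is_decoy")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    return(sprintf("missing rowData column(s): %s", paste(miss, collapse = ", ")))
  sig <- assay(object, "signal")
  if (any(!is.finite(sig)) || any(sig < 0))
    return("assay 'signal' must be finite and non-negative")
  npep <- rd$n_peptides
  nz <- rowSums(sig) > 0
  if (any(nz & (is.na(npep) | npep < 1L)))
    return("n_peptides must be >= 1 for records with nonzero signal")
  TRUE
})

#' Per-channel mixing-correction factors
#'
#' Median-of-ratio correction factors: for each channel the median, over
#' peptides quantified in every channel, of that peptide's intensity divided
#' by its cross-channel mean intensity. Dividing a channel by its factor
#' equalizes channel loading.
#'
#' @slot factors Named positive numeric, one factor per channel.
#' @slot nPeptidesUsed Number of complete peptide rows the estimate used.
#' @slot qcBand Two-element numeric; factors outside it are QC-flagged.
#' @slot withinBand Named logical, per-channel QC flag.
#' @seealso [mixingCorrectionFactors()], [applyCorrection()]
#' @export
setClass("MixingCorrection",
         representation(factors = "numeric", nPeptidesUsed = "integer",
                        qcBand = "numeric", withinBand = "logical"))

setValidity("MixingCorrection", function(object) {
  f <- object@factors
  if (is.null(names(f)) || anyDuplicated(names(f)))
    return("factors must be uniquely named by channel_id")
  if (any(!is.finite(f)) || any(f <= 0)) return("all factors must be finite and > 0")
  if (length(object@qcBand) != 2L || object@qcBand[1] >= object@qcBand[2])
    return("qcBand must be an increasing pair")
  TRUE
})

#' IgG-normalized fold-enrichment table
#'
#' Holds E[p, s]: the relative abundance of protein p in non-IgG sample s
#' divided by its relative abundance in the chemistry-matched IgG control
#' (with a pseudocount floor on the control abundance so ratios stay finite).
#'
#' @slot ratios Numeric matrix, proteins x non-IgG samples; \code{NA} only
#'   under the \code{"drop"} pseudocount policy.
#' @slot nPeptides Named integer, peptides per protein.
#' @slot pseudocount Named numeric, the abundance floor applied per IgG
#'   control channel.
#' @slot design The [CoipDesign-class].
#' @seealso [enrichmentRatios()], [deriveCutoffs()], [enrichedSet()]
#' @export
setClass("EnrichmentTable",
         representation(ratios = "matrix", nPeptides = "integer",
                        pseudocount = "numeric", design = "CoipDesign"))

setValidity("EnrichmentTable", function(object) {
  r <- object@ratios
  if (!is.numeric(r)) return("ratios must be numeric")
  if (is.null(rownames(r)) || is.null(colnames(r)))
    return("ratios must have protein rownames and sample colnames")
  if (any(r[!is.na(r)] < 0)) return("ratios must be non-negative")
  if (any(is.infinite(r), na.rm = TRUE)) return("ratios must be finite")
  samp <- nonIggSamples(object@design)
  if (!all(colnames(r) %in% samp))
    return("ratio columns must be non-IgG samples of the design")
  if (!identical(sort(names(object@nPeptides)), sort(rownames(r))))
    return("nPeptides must be named by the ratio rownames")
  TRUE
})

#' Fold-enrichment cutoffs
#'
#' The empirical quantile-derived fold-enrichment threshold per pooling group
#' (bead chemistry by default), with the quantile level and minimum-peptide
#' filter used to derive it.
#'
#' @slot theta Named positive numeric: cutoff per chemistry (scope
#'   \code{"chemistry"}) or per sample (scope \code{"sample"}).
#' @slot q Quantile level in (0, 1) (default 0.95: "top 5%").
#' @slot minPeptides Minimum peptides for a protein to enter cutoff pools and
#'   enriched sets.
#' @slot scope Either \code{"chemistry"} or \code{"sample"}.
#' @seealso [deriveCutoffs()], [enrichedSet()]
#' @export
setClass("CutoffSet",
         representation(theta = "numeric", q = "numeric",
                        minPeptides = "integer", scope = "character"))

setValidity("CutoffSet", function(object) {
  if (any(!is.finite(object@theta)) || any(object@theta <= 0))
    return("theta must be finite and > 0")
  if (is.null(names(object@theta))) return("theta must be named")
  if (length(object@q) != 1L || object@q <= 0 || object@q >= 1)
    return("q must be a single value in (0, 1)")
  if (length(object@minPeptides) != 1L || object@minPeptides < 1L)
    return("minPeptides must be a single integer >= 1")
  if (!object@scope %in% c("chemistry", "sample"))
    return("scope must be 'chemistry' or 'sample'")
  TRUE
})

#' Assembled interactome and restricted background
#'
#' Per-sample enriched protein sets together with the interactome (union of
#' enriched sets over bait samples) and the restricted background (union over
#' all non-IgG samples), which is the universe for overlap and annotation
#' statistics.
#'
#' @slot enrichedSets Named list of character vectors, one per non-IgG sample.
#' @slot interactome Character vector of protein ids.
#' @slot background Character vector of protein ids; contains the interactome.
#' @slot cutoffs The [CutoffSet-class] used.
#' @slot strict Logical; \code{TRUE} means strict ">" threshold comparison.
#' @slot design The [CoipDesign-class].
#' @seealso [assembleInteractome()], [pairwiseOverlapMatrix()]
#' @export
setClass("InteractomeResult",
         representation(enrichedSets = "list", interactome = "character",
                        background = "character", cutoffs = "CutoffSet",
                        strict = "logical", design = "CoipDesign"))

setValidity("InteractomeResult", function(object) {
  samp <- nonIggSamples(object@design)
  if (!identical(sort(names(object@enrichedSets)), sort(samp)))
    return("enrichedSets must cover exactly the non-IgG samples")
  baits <- baitSamples(object@design)
  want <- sort(unique(unlist(object@enrichedSets[baits], use.names = FALSE)))
  if (!identical(sort(object@interactome), want))
    return("interactome must equal the union of enriched sets over bait samples")
  wantbg <- sort(unique(unlist(object@enrichedSets, use.names = FALSE)))
  if (!identical(sort(object@background), wantbg))
    return("background must equal the union of enriched sets over all non-IgG samples")
  if (!all(object@interactome %in% object@background))
    return("interactome must be a subset of the background")
  TRUE
})

#' Synthetic 10-plex co-IP generator configuration
#'
#' Parameters of the generative model behind [simulateCoip()]. Protein base
#' abundances are log-normal; planted interactors get elevated capture in
#' their bait channels; nonspecific binders are elevated in every channel
#' including the IgG controls; per-channel loading imbalance and
#' multiplicative noise are applied; peptide counts follow a saturating
#' detectability model. See the package vignette for the full model.
#'
#' @seealso [simulationConfig()], [simulateCoip()]
#' @export
setClass("SimulationConfig",
         representation(nProteins = "integer", nTruePerBait = "integer",
                        nNonspecific = "integer", nContaminants = "integer",
                        interactorPoolSize = "integer",
                        bindingFoldTrue = "numeric", nonspecificFold = "numeric",
                        backgroundScale = "numeric",
                        abundanceLogmean = "numeric", abundanceLogsd = "numeric",
                        poolLogBoost = "numeric", noiseCv = "numeric",
                        mixingFactors = "numeric",
                        peptideMean = "numeric", detectMid = "numeric",
                        detectShape = "numeric", psmsPerPeptide = "integer",
                        labelEfficiency = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nProteins < 1L) return("nProteins must be >= 1")
  if (object@bindingFoldTrue < 1) return("bindingFoldTrue must be >= 1")
  if (object@nonspecificFold < 1) return("nonspecificFold must be >= 1")
  if (any(object@backgroundScale <= 0)) return("backgroundScale entries must be > 0")
  if (!all(.CHEMISTRIES %in% names(object@backgroundScale)))
    return("backgroundScale must be named for every chemistry")
  if (object@noiseCv < 0) return("noiseCv must be >= 0")
  if (length(object@mixingFactors) && any(object@mixingFactors <= 0))
    return("mixingFactors must be > 0")
  if (object@peptideMean < 1) return("peptideMean must be >= 1")
  if (object@psmsPerPeptide < 1L) return("psmsPerPeptide must be >= 1")
  if (object@labelEfficiency < 0 || object@labelEfficiency > 1)
    return("labelEfficiency must be in [0, 1]")
  if (object@interactorPoolSize < object@nTruePerBait)
    return("interactorPoolSize must be >= nTruePerBait")
  TRUE
})

#' Planted ground truth of a synthetic experiment
#'
#' @slot trueInteractors Named list: for each non-IgG sample, the protein ids
#'   planted as specifically captured in that sample's channel.
#' @slot nonspecific Protein ids elevated in all channels including IgG.
#' @slot lambda Named numeric base abundances.
#' @slot peptides Named integer peptide counts.
#' @slot expectedSignal Noise-free expected protein x channel signal matrix
#'   (the simulator's bookkeeping record; PSM aggregation must reproduce the
#'   realized matrix, and equals this exactly when \code{noiseCv} is 0).
#' @seealso [simulateCoip()], [scoreRecovery()]
#' @export
setClass("GroundTruth",
         representation(trueInteractors = "list", nonspecific = "character",
                        lambda = "numeric", peptides = "integer",
                        expectedSignal = "matrix"))

setValidity("GroundTruth", function(object) {
  planted <- unique(unlist(object@trueInteractors, use.names = FALSE))
  if (length(intersect(planted, object@nonspecific)))
    return("planted interactor sets and nonspecific set must be disjoint")
  TRUE
})

#' Recovery of the planted truth by the pipeline
#'
#' Precision, recall and F1 of the assembled interactome against the union of
#' planted interactor sets over bait samples. Precision of an empty
#' interactome is 1 by convention and flagged via \code{emptyInteractome}.
#'
#' @seealso [scoreRecovery()]
#' @export
setClass("RecoveryMetrics",
         representation(precision = "numeric", recall = "numeric", f1 = "numeric",
                        falsePositives = "character", falseNegatives = "character",
                        emptyInteractome = "logical"))
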