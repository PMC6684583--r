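#' Accessors for design and result objects
#'
#' Small camelCase accessors that expose the slots of [CoipDesign-class],
#' [EnrichmentTable-class], [CutoffSet-class], [InteractomeResult-class] and
#' [RecoveryMetrics-class] without touching slots directly.
#'
#' @param x A package object of the matching class.
#' @param chemistry One of \code{"agarose"}, \code{"magnetic"}.
#' @return See individual functions.
#' @name accessors
NULL

#' @describeIn accessors Channel identifiers, in design order.
#' @export
channelIds <- function(x) as.character(x@channels$channel_id)

#' @describeIn accessors Sample names, in design order.
#' @export
sampleNames <- function(x) as.character(x@channels$sample_name)

#' @describeIn accessors The design's channel table as a data.frame.
#' @export
designTable <- function(x) as.data.frame(x@channels)

#' @describeIn accessors Sample names of bait IPs (the bait group).
#' @export
baitSamples <- function(x) {
  ch <- x@channels
  as.character(ch$sample_name[ch$role == "bait"])
}

#' @describeIn accessors Sample names of all non-IgG IPs (baits and unrelated
#'   controls), in design order.
#' @export
nonIggSamples <- function(x) {
  ch <- x@channels
  as.character(ch$sample_name[ch$role != "igg_control"])
}

#' @describeIn accessors Map chemistry -> IgG-control sample name.
#' @export
controlMatching <- function(x) {
  ch <- x@channels
  igg <- ch[ch$role == "igg_control", , drop = FALSE]
  structure(as.character(igg$sample_name), names = as.character(igg$chemistry))
}

#' @describeIn accessors Channel id of the IgG control for a chemistry.
#' @export
iggChannel <- function(x, chemistry) {
  ch <- x@channels
  hit <- ch$role == "igg_control" & ch$chemistry == chemistry
  if (!any(hit)) stop("no igg_control channel for chemistry '", chemistry, "'")
  as.character(ch$channel_id[hit])
}

#' @describeIn accessors Channel id carrying a given sample.
#' @export
sampleChannel <- function(x, sample) {
  ch <- x@channels
  hit <- match(sample, ch$sample_name)
  if (anyNA(hit)) stop("unknown sample(s): ",
                       paste(sample[is.na(hit)], collapse = ", "))
  as.character(ch$channel_id[hit])
}

#' @describeIn accessors Bead chemistry of a given sample.
#' @export
sampleChemistry <- function(x, sample) {
  ch <- x@channels
  hit <- match(sample, ch$sample_name)
  if (anyNA(hit)) stop("unknown sample(s): ",
                       paste(sample[is.na(hit)], collapse = ", "))
  as.character(ch$chemistry[hit])
}

#' @describeIn accessors The design attached to an object.
#' @export
coipDesign <- function(x) x@design

#' @describeIn accessors Fold-enrichment ratio matrix of an
#'   [EnrichmentTable-class] (proteins x non-IgG samples).
#' @export
enrichmentMatrix <- function(x) x@ratios

#' @describeIn accessors Named peptide counts of an [EnrichmentTable-class].
#' @export
peptideCounts <- function(x) x@nPeptides

#' @describeIn accessors Pseudocount floors applied per IgG channel.
#' @export
pseudocountUsed <- function(x) x@pseudocount

#' @describeIn accessors Named cutoff vector of a [CutoffSet-class].
#' @export
cutoffTheta <- function(x) x@theta

#' @describeIn accessors Per-sample enriched sets of an
#'   [InteractomeResult-class].
#' @export
enrichedSets <- function(x) x@enrichedSets

#' @describeIn accessors The assembled interactome (protein ids).
#' @export
interactome <- function(x) x@interactome

#' @describeIn accessors The restricted background (protein ids).
#' @export
interactomeBackground <- function(x) x@background

#' @describeIn accessors Correction factors of a [MixingCorrection-class].
#' @export
correctionFactors <- function(x) x@factors

setMethod("show", "CoipDesign", function(object) {
  ch <- object@channels
  cat(sprintf("CoipDesign: %d channels (%d bait, %d unrelated, %d IgG)\n",
              nrow(ch), sum(ch$role == "bait"),
              sum(ch$role == "unrelated_control"),
              sum(ch$role == "igg_control")))
  print(as.data.frame(ch), row.names = FALSE)
})

setMethod("show", "MixingCorrection", function(object) {
  cat(sprintf("MixingCorrection over %d complete peptide rows\n",
              object@nPeptidesUsed))
  print(round(object@factors, 4))
  out <- names(object@withinBand)[!object@withinBand]
  if (length(out))
    cat(sprintf("outside QC band [%.2f, %.2f]: %s\n",
                object@qcBand[1], object@qcBand[2], paste(out, collapse = ", ")))
})

setMethod("show", "EnrichmentTable", function(object) {
  cat(sprintf("EnrichmentTable: %d proteins x %d IP samples\n",
              nrow(object@ratios), ncol(object@ratios)))
  cat("samples:", paste(colnames(object@ratios), collapse = ", "), "\n")
  cat("pseudocount floors:",
      paste(sprintf("%s=%.3g", names(object@pseudocount), object@pseudocount),
            collapse = ", "), "\n")
})

setMethod("show", "CutoffSet", function(object) {
  cat(sprintf("CutoffSet (top %.0f%%, >=%d peptides, per %s):\n",
              100 * (1 - object@q), object@minPeptides, object@scope))
  print(round(object@theta, 3))
})

setMethod("show", "InteractomeResult", function(object) {
  cat(sprintf("InteractomeResult: interactome %d proteins, background %d proteins\n",
              length(object@interactome), length(object@background)))
  sizes <- vapply(object@enrichedSets, length, integer(1))
  cat("enriched per sample:\n")
  print(sizes)
})

setMethod("show", "RecoveryMetrics", function(object) {
  cat(sprintf("RecoveryMetrics: precision %.3f, recall %.3f, F1 %.3f (FP %d, FN %d)%s\n",
              object@precision, object@recall, object@f1,
              length(object@falsePositives), length(object@falseNegatives),
              if (object@emptyInteractome) " [empty interactome]" else ""))
})

setMethod("show", "GroundTruth", function(object) {
  sizes <- vapply(object@trueInteractors, length, integer(1))
  cat(sprintf("GroundTruth: %d nonspecific binders; planted per sample:\n",
              length(object@nonspecific)))
  print(sizes)
})
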