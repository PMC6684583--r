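#' TMT labeling efficiency
#'
#' Fraction of PSMs carrying an isobaric label on the peptide N-terminus or a
#' lysine, from a labeling-check run. A channel passes QC when the fraction
#' meets the threshold (0.96 by default, i.e. "96% or greater").
#'
#' @param psms A PSM data.frame with logical columns \code{has_nterm_label}
#'   and \code{has_lysine_label} (see [readPsmTable()]).
#' @param threshold QC gate on the labeled fraction.
#' @return A list with \code{efficiency} (in \[0, 1\]), \code{pass},
#'   \code{n_psms} and \code{threshold}.
#' @examples
#' psms <- data.frame(has_nterm_label = c(TRUE, TRUE, FALSE),
#'                    has_lysine_label = c(FALSE, TRUE, FALSE))
#' labelingEfficiency(psms)$efficiency  # 2/3
#' @export
labelingEfficiency <- function(psms, threshold = 0.96) {
  if (is.null(psms) || nrow(psms) == 0L)
    stop("labeling efficiency is undefined on an empty PSM set")
  lab <- psms$has_nterm_label | psms$has_lysine_label
  eff <- mean(lab)
  list(efficiency = eff, pass = eff >= threshold,
       n_psms = nrow(psms), threshold = threshold)
}

#' Peptide x channel total-signal matrix from PSMs
#'
#' Sums reporter intensity times injection time over the PSMs of each
#' peptide sequence; the input to [mixingCorrectionFactors()].
#'
#' @param psms PSM data.frame from [readPsmTable()] or [simulateCoip()].
#' @param design A [CoipDesign-class].
#' @return Numeric matrix, peptides x channels.
#' @export
peptideMatrix <- function(psms, design) {
  ids <- channelIds(design)
  cols <- paste0("intensity.", ids)
  miss <- setdiff(cols, colnames(psms))
  if (length(miss))
    stop("PSM table lacks intensity column(s): ", paste(miss, collapse = ", "))
  total <- as.matrix(psms[, cols, drop = FALSE]) * psms$injection_time
  out <- rowsum(total, group = psms$peptide_sequence)
  colnames(out) <- ids
  out
}

#' Median-of-ratio mixing-correction factors
#'
#' For each channel c, the factor is the median over complete peptide rows i
#' (all channels > 0) of \eqn{x_{i,c} / \mathrm{mean}_{c'} x_{i,c'}}. Factors
#' near 1 indicate balanced channel loading; the QC band (default
#' \[0.90, 1.10\]) flags channels needing correction.
#'
#' @param mat Numeric peptide x channel matrix (named columns).
#' @param qcBand Length-2 numeric QC band for the factors.
#' @return A [MixingCorrection-class].
#' @examples
#' m <- matrix(rep(c(2, 1, 1), each = 5), ncol = 3,
#'             dimnames = list(NULL, c("A", "B", "C")))
#' correctionFactors(mixingCorrectionFactors(m))  # 1.5, 0.75, 0.75
#' @export
mixingCorrectionFactors <- function(mat, qcBand = c(0.90, 1.10)) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  complete <- rowSums(!is.finite(mat) | mat <= 0) == 0L
  if (!any(complete))
    stop("cannot estimate mixing factors: no peptide row is quantified in all channels")
  x <- mat[complete, , drop = FALSE]
  ratios <- x / rowMeans(x)
  f <- apply(ratios, 2L, stats::median)
  new("MixingCorrection", factors = f, nPeptidesUsed = sum(complete),
      qcBand = as.numeric(qcBand),
      withinBand = f >= qcBand[1] & f <= qcBand[2])
}

#' Apply mixing correction to an intensity matrix
#'
#' Divides each channel by its correction factor, the data-level equivalent
#' of re-mixing channel volumes so median ratios return to 1. On a complete
#' matrix whose channel imbalance is a pure per-channel scaling, recomputing
#' [mixingCorrectionFactors()] on the output yields factors equal to 1 to
#' floating-point precision.
#'
#' @param mat Numeric matrix with channel columns.
#' @param correction A [MixingCorrection-class] (or named positive numeric)
#'   covering all columns of \code{mat}.
#' @return The corrected matrix.
#' @export
applyCorrection <- function(mat, correction) {
  f <- if (is(correction, "MixingCorrection")) correction@factors else correction
  if (any(!is.finite(f)) || any(f <= 0)) stop("correction factors must be > 0")
  miss <- setdiff(colnames(mat), names(f))
  if (length(miss))
    stop("no correction factor for channel(s): ", paste(miss, collapse = ", "))
  sweep(mat, 2L, f[colnames(mat)], "/")
}

#' Aggregate PSMs into protein x channel total signal
#'
#' The total reporter signal of protein p in channel c is the sum over p's
#' PSMs of reporter intensity times ion injection time; the peptide count is
#' the number of distinct peptide sequences. PSMs with a missing/empty
#' protein assignment are skipped with a warning stating how many.
#' Contaminant and decoy protein groups are recognized by the conventional
#' \code{CON__} / \code{REV__} id prefixes and flagged (not removed).
#'
#' @param psms PSM data.frame (see [readPsmTable()]).
#' @param design A [CoipDesign-class].
#' @return A [CoipExperiment-class].
#' @examples
#' d <- CoipDesign("126", "IgG.ag", "IgG", "agarose", "igg_control")
#' psms <- data.frame(psm_id = c("s1", "s2"), protein_id = "P1",
#'                    peptide_sequence = c("PEPA", "PEPB"),
#'                    injection_time = 0.05,
#'                    has_nterm_label = TRUE, has_lysine_label = FALSE,
#'                    `intensity.126` = c(1000, 2000), check.names = FALSE)
#' assay(proteinSignalFromPsms(psms, d))  # 150
#' @export
proteinSignalFromPsms <- function(psms, design) {
  stopifnot(is(design, "CoipDesign"))
  ids <- channelIds(design)
  cols <- paste0("intensity.", ids)
  miss <- setdiff(cols, colnames(psms))
  if (length(miss))
    stop("PSM table lacks intensity column(s): ", paste(miss, collapse = ", "))
  orphan <- is.na(psms$protein_id) | !nzchar(trimws(psms$protein_id))
  if (any(orphan)) {
    warning(sum(orphan), " PSM(s) reference no protein and were skipped")
    psms <- psms[!orphan, , drop = FALSE]
  }
  if (!nrow(psms)) stop("no PSMs with protein assignments")
  total <- as.matrix(psms[, cols, drop = FALSE]) * psms$injection_time
  sig <- rowsum(total, group = psms$protein_id)
  colnames(sig) <- ids
  pep <- tapply(psms$peptide_sequence, psms$protein_id,
                function(s) length(unique(s)))
  pep <- as.integer(pep[rownames(sig)])
  CoipExperiment(sig, design, nPeptides = pep,
                 isContaminant = startsWith(rownames(sig), "CON__"),
                 isDecoy = startsWith(rownames(sig), "REV__"))
}
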