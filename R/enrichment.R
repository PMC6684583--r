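#' Within-channel relative abundance
#'
#' Converts total signal to each protein's share of its channel's total:
#' \eqn{a_{p,c} = S_{p,c} / \sum_{p'} S_{p',c}}. Contaminant and decoy rows
#' are removed first (by default) so shares refer to the biological protein
#' population; every channel column of the result sums to 1.
#'
#' @param x A [CoipExperiment-class] with a \code{"signal"} assay.
#' @param keepContaminants Keep contaminant/decoy rows (default FALSE).
#' @return \code{x}, row-filtered, with a \code{"relabund"} assay added.
#' @examples
#' d <- CoipDesign(c("126", "127N"), c("IgG.ag", "Bait.ag"), c("IgG", "mAb"),
#'                 c("agarose", "agarose"), c("igg_control", "bait"))
#' sig <- matrix(c(3, 1, 1, 1), 2, 2, dimnames = list(c("P1", "P2"), c("126", "127N")))
#' assay(relativeAbundance(CoipExperiment(sig, d, c(3L, 3L))), "relabund")
#' @export
relativeAbundance <- function(x, keepContaminants = FALSE) {
  stopifnot(is(x, "CoipExperiment"))
  if (!keepContaminants) {
    rd <- rowData(x)
    x <- x[!(rd$is_contaminant | rd$is_decoy), ]
  }
  sig <- assay(x, "signal")
  if (!nrow(sig)) stop("no proteins left after contaminant/decoy filtering")
  tot <- colSums(sig)
  zero <- tot <= 0
  if (any(zero))
    stop("degenerate channel(s) with zero total signal: ",
         paste(colnames(sig)[zero], collapse = ", "))
  assay(x, "relabund") <- sweep(sig, 2L, tot, "/")
  x
}

#' IgG-normalized fold-enrichment ratios
#'
#' For every non-IgG sample s, \eqn{E_{p,s} = a_{p,s} / \max(a_{p,igg(s)},
#' \epsilon)}, where igg(s) is the IgG control matched to s's bead chemistry
#' and \eqn{\epsilon} is a per-IgG-channel floor keeping ratios finite when a
#' protein is absent from the control. Policies: \code{"halfmin"} (default;
#' half the smallest nonzero relative abundance in that IgG channel),
#' \code{"fixed"} (a supplied \code{eps}), \code{"drop"} (proteins with zero
#' control abundance get \code{NA} and take no part in cutoffs or sets).
#'
#' @param x A [CoipExperiment-class]; [relativeAbundance()] is applied if the
#'   \code{"relabund"} assay is absent.
#' @param pseudocount Pseudocount policy, see above.
#' @param eps Floor value when \code{pseudocount = "fixed"}.
#' @return An [EnrichmentTable-class].
#' @export
enrichmentRatios <- function(x, pseudocount = c("halfmin", "fixed", "drop"),
                             eps = NULL) {
  stopifnot(is(x, "CoipExperiment"))
  pseudocount <- match.arg(pseudocount)
  if (!"relabund" %in% assayNames(x)) x <- relativeAbundance(x)
  ab <- assay(x, "relabund")
  design <- x@design
  samples <- nonIggSamples(design)
  if (!length(samples)) stop("design has no non-IgG samples")
  match_ctrl <- controlMatching(design)
  chems <- sampleChemistry(design, samples)
  miss <- setdiff(unique(chems), names(match_ctrl))
  if (length(miss))
    stop("no IgG control for chemistry: ", paste(miss, collapse = ", "))

  floors <- numeric(0)
  ctrl_ab <- list()
  for (chem in unique(chems)) {
    igg_ch <- iggChannel(design, chem)
    a_igg <- ab[, igg_ch]
    epsc <- switch(pseudocount,
      halfmin = {
        nz <- a_igg[a_igg > 0]
        if (!length(nz)) stop("IgG channel '", igg_ch, "' has no nonzero abundance")
        min(nz) / 2
      },
      fixed = {
        if (is.null(eps) || eps <= 0) stop("pseudocount='fixed' needs eps > 0")
        eps
      },
      drop = NA_real_)
    floors[igg_ch] <- epsc
    ctrl_ab[[chem]] <- a_igg
  }

  ratios <- matrix(NA_real_, nrow(ab), length(samples),
                   dimnames = list(rownames(ab), samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    a_s <- ab[, sampleChannel(design, s)]
    a_igg <- ctrl_ab[[chems[k]]]
    if (pseudocount == "drop") {
      denom <- ifelse(a_igg > 0, a_igg, NA_real_)
    } else {
      denom <- pmax(a_igg, floors[iggChannel(design, chems[k])])
    }
    ratios[, k] <- a_s / denom
  }
  npep <- rowData(x)$n_peptides
  names(npep) <- rownames(ab)
  new("EnrichmentTable", ratios = ratios, nPeptides = as.integer(npep) |>
        stats::setNames(rownames(ab)),
      pseudocount = floors, design = design)
}

#' Derive top-quantile fold-enrichment cutoffs
#'
#' Pools enrichment ratios across all samples of each bead chemistry (or per
#' sample, with \code{scope = "sample"}) and takes the empirical quantile at
#' \code{q} (default 0.95, the "top 5%" convention) as that group's cutoff.
#' Quantiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7), so cutoffs are bit-reproducible. By
#' default only proteins meeting the minimum-peptide filter enter the pools
#' (\code{filterFirst = TRUE}).
#'
#' @param enrichment An [EnrichmentTable-class].
#' @param q Quantile level in (0, 1).
#' @param minPeptides Minimum peptide count (default 3).
#' @param scope Pool per \code{"chemistry"} (default) or per \code{"sample"}.
#' @param filterFirst Apply the peptide filter before pooling.
#' @param minValues Minimum pooled values per group (default 20); fewer is an
#'   insufficient-data error.
#' @return A [CutoffSet-class].
#' @examples
#' # 20 identical values give their common value; 1..20 at q = 0.95 gives 19.05
#' @export
deriveCutoffs <- function(enrichment, q = 0.95, minPeptides = 3L,
                          scope = c("chemistry", "sample"),
                          filterFirst = TRUE, minValues = 20L) {
  stopifnot(is(enrichment, "EnrichmentTable"))
  scope <- match.arg(scope)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  rat <- enrichment@ratios
  if (filterFirst) {
    keep <- enrichment@nPeptides[rownames(rat)] >= minPeptides
    rat <- rat[keep, , drop = FALSE]
  }
  design <- enrichment@design
  groups <- switch(scope,
    chemistry = sampleChemistry(design, colnames(rat)),
    sample = colnames(rat))
  theta <- numeric(0)
  for (g in unique(groups)) {
    vals <- rat[, groups == g, drop = FALSE]
    vals <- vals[!is.na(vals)]
    if (length(vals) < minValues)
      stop(sprintf("insufficient data for cutoff '%s': %d pooled values (< %d)",
                   g, length(vals), minValues))
    theta[g] <- unname(stats::quantile(vals, probs = q, type = 7))
  }
  new("CutoffSet", theta = theta, q = q,
      minPeptides = as.integer(minPeptides), scope = scope)
}

.theta_for <- function(cutoffs, design, sample) {
  key <- switch(cutoffs@scope,
                chemistry = sampleChemistry(design, sample),
                sample = sample)
  if (!key %in% names(cutoffs@theta))
    stop("no cutoff available for '", key, "'")
  cutoffs@theta[[key]]
}

#' Enriched protein set of one IP sample
#'
#' Proteins quantified by at least \code{minPeptides} peptides whose fold
#' enrichment exceeds the sample's cutoff. The comparison is strict
#' (\code{>}) by default; \code{strict = FALSE} uses \code{>=}.
#'
#' @param enrichment An [EnrichmentTable-class].
#' @param cutoffs A [CutoffSet-class].
#' @param sample A non-IgG sample name of the design.
#' @param strict Strict threshold comparison (default TRUE).
#' @return Character vector of protein ids.
#' @export
enrichedSet <- function(enrichment, cutoffs, sample, strict = TRUE) {
  stopifnot(is(enrichment, "EnrichmentTable"), is(cutoffs, "CutoffSet"))
  rat <- enrichment@ratios
  if (!sample %in% colnames(rat)) stop("unknown sample: ", sample)
  theta <- .theta_for(cutoffs, enrichment@design, sample)
  e <- rat[, sample]
  npep <- enrichment@nPeptides[rownames(rat)]
  hit <- !is.na(e) & npep >= cutoffs@minPeptides &
    (if (strict) e > theta else e >= theta)
  rownames(rat)[hit]
}

#' Assemble the interactome and restricted background
#'
#' Computes the enriched set of every non-IgG sample, defines the interactome
#' as the union over bait samples and the restricted background as the union
#' over all non-IgG samples (so the interactome is always contained in the
#' background).
#'
#' @param enrichment An [EnrichmentTable-class].
#' @param cutoffs A [CutoffSet-class] (e.g. from [deriveCutoffs()]).
#' @param strict Strict threshold comparison (default TRUE).
#' @return An [InteractomeResult-class].
#' @export
assembleInteractome <- function(enrichment, cutoffs, strict = TRUE) {
  stopifnot(is(enrichment, "EnrichmentTable"))
  design <- enrichment@design
  baits <- baitSamples(design)
  if (!length(baits)) stop("design has an empty bait group")
  samples <- nonIggSamples(design)
  sets <- lapply(samples, function(s) enrichedSet(enrichment, cutoffs, s, strict))
  names(sets) <- samples
  ids <- rownames(enrichment@ratios)
  inter <- ids[ids %in% unlist(sets[baits], use.names = FALSE)]
  backg <- ids[ids %in% unlist(sets, use.names = FALSE)]
  new("InteractomeResult", enrichedSets = sets, interactome = inter,
      background = backg, cutoffs = cutoffs, strict = strict, design = design)
}
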