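#' 2x2 overlap contingency table on a restricted background
#'
#' Entries: \code{a} = |A intersect B|, \code{b} = |A \\ B|, \code{c} =
#' |B \\ A|, \code{d} = |background \\ (A union B)|; they always sum to the
#' background size. Both sets must lie inside the background.
#'
#' @param setA,setB Character vectors of protein ids.
#' @param background Character vector, the restricted universe.
#' @return Named integer vector \code{c(a, b, c, d)}.
#' @examples
#' overlapContingency(c("x", "y"), c("x", "y"), c("x", "y", "z", "w"))  # 2,0,0,2
#' @export
overlapContingency <- function(setA, setB, background) {
  setA <- unique(setA); setB <- unique(setB); background <- unique(background)
  out <- setdiff(union(setA, setB), background)
  if (length(out))
    stop("set member(s) outside the background: ", paste(out, collapse = ", "))
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  cc <- length(setB) - a
  d <- length(background) - a - b - cc
  c(a = a, b = b, c = cc, d = as.integer(d))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p-value with fixed margins: the sum of hypergeometric point
#' probabilities of all tables at least as extreme as the observed one,
#' where "as extreme" means point probability no larger than the observed
#' table's (the convention of standard exact-test implementations, with the
#' usual 1 + 1e-7 relative tolerance for ties). Point probabilities come
#' from the hypergeometric density evaluated in log space, so backgrounds of
#' a few hundred proteins pose no overflow risk. The odds ratio is the
#' sample odds ratio ad/bc, reported as \code{Inf} when bc = 0 (and
#' \code{NaN} when the table is degenerate with ad = 0 as well).
#'
#' @param table Named or ordered integer vector \code{c(a, b, c, d)} (or a
#'   2x2 matrix, read column-wise a, c, b, d as \code{matrix(c(a,c,b,d),2)}).
#' @return List with \code{p} in (0, 1] and \code{odds_ratio}.
#' @examples
#' fisherTwoSided(c(2, 2, 2, 2))$p            # 1
#' fisherTwoSided(c(5, 0, 0, 5))$p * 252      # 2
#' @export
fisherTwoSided <- function(table) {
  if (is.matrix(table)) table <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  if (length(table) != 4L) stop("table must have four entries a, b, c, d")
  if (any(is.na(table)) || any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers")
  a <- table[[1]]; b <- table[[2]]; cc <- table[[3]]; d <- table[[4]]
  m <- a + b          # size of set A
  n <- cc + d         # complement of A
  k <- a + cc         # size of set B
  support <- max(0L, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- logp[match(a, support)]
  p <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  p <- min(1, max(p, exp(obs)))
  or <- if (b == 0 || cc == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  list(p = p, odds_ratio = or)
}

#' Significance code for a p-value
#'
#' \code{"***"} for p < 0.001, \code{"**"} for p < 0.01, \code{"*"} for
#' p < 0.05, \code{"ns"} otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of codes.
#' @export
significanceCode <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Pairwise overlap-specificity matrix against a reference sample
#'
#' For every non-reference enriched set, the 2x2 overlap table with the
#' reference set on the restricted background, the two-sided Fisher exact
#' p-value, the sample odds ratio, and a significance code. Rows follow the
#' design/list order, so output is deterministic. No multiple-testing
#' correction is applied by default (raw significance codes);
#' \code{adjust = "BH"} adds a Benjamini-Hochberg column and codes on the
#' adjusted values.
#'
#' @param x An [InteractomeResult-class], or a named list of enriched sets
#'   (then \code{background} is required).
#' @param reference Name of the reference sample (default for an
#'   [InteractomeResult-class]: the first agarose bait in design order).
#' @param background Character vector when \code{x} is a plain list.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return A data.frame with columns \code{sample_a}, \code{sample_b},
#'   \code{a}, \code{b}, \code{c}, \code{d}, \code{odds_ratio}, \code{p},
#'   (\code{p_adj}), \code{code}.
#' @export
pairwiseOverlapMatrix <- function(x, reference = NULL, background = NULL,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is(x, "InteractomeResult")) {
    sets <- x@enrichedSets
    background <- x@background
    if (is.null(reference)) {
      design <- x@design
      baits <- baitSamples(design)
      agarose <- baits[sampleChemistry(design, baits) == "agarose"]
      reference <- if (length(agarose)) agarose[1] else baits[1]
    }
  } else {
    sets <- x
    if (is.null(background)) stop("background is required for a plain set list")
    if (is.null(reference)) stop("reference is required for a plain set list")
  }
  if (!reference %in% names(sets))
    stop("reference sample '", reference, "' is not among the enriched sets")
  others <- setdiff(names(sets), reference)
  rows <- lapply(others, function(s) {
    tab <- overlapContingency(sets[[reference]], sets[[s]], background)
    ft <- fisherTwoSided(tab)
    data.frame(sample_a = reference, sample_b = s,
               a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$code <- significanceCode(out$p_adj)
  } else {
    out$code <- significanceCode(out$p)
  }
  rownames(out) <- NULL
  out
}

#' Annotation-set over-representation on the restricted background
#'
#' One-sided (greater) hypergeometric tail test of each annotation set's
#' overlap with a target set, both intersected with the restricted
#' background. \code{fold} is observed over expected overlap
#' (|A||T|/N). Optional Benjamini-Hochberg adjustment across annotations.
#'
#' @param targetSet Character vector (e.g. the interactome).
#' @param annotationSets Named list of character vectors (see
#'   [readAnnotationSets()]).
#' @param background Character vector, the restricted universe.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return A data.frame with one row per annotation: sizes, overlap,
#'   \code{expected}, \code{fold}, \code{p} (and \code{p_adj}).
#' @export
annotationEnrichment <- function(targetSet, annotationSets, background,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  background <- unique(background)
  N <- length(background)
  if (!N) stop("background is empty")
  target <- intersect(unique(targetSet), background)
  nT <- length(target)
  rows <- lapply(names(annotationSets), function(nm) {
    ann <- intersect(unique(annotationSets[[nm]]), background)
    nA <- length(ann)
    ov <- length(intersect(ann, target))
    expected <- nA * nT / N
    p <- stats::phyper(ov - 1L, nA, N - nA, nT, lower.tail = FALSE)
    data.frame(annotation = nm, n_annotation = nA, n_target = nT,
               overlap = ov, expected = expected,
               fold = if (expected > 0) ov / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
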