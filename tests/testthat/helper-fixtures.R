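suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# minimal legal design: one IgG control, one bait, one unrelated (agarose)
design3 <- function() {
  CoipDesign(channel_id = c("126", "127N", "127C"),
             sample_name = c("IgG.ag", "Bait.ag", "Unrel.ag"),
             antibody = c("IgG", "mAb1", "mAb2"),
             chemistry = rep("agarose", 3),
             role = c("igg_control", "bait", "unrelated_control"))
}

# small experiment from an explicit signal matrix on design3()
experiment3 <- function(signal, nPeptides = rep(3L, nrow(signal))) {
  CoipExperiment(signal, design3(), nPeptides = nPeptides)
}

# brute-force per-row mixing factors: median over complete rows of
# ratio-to-row-mean, written as an explicit loop (independent of the
# vectorized implementation)
bruteMixingFactors <- function(mat) {
  keep <- apply(mat, 1L, function(r) all(is.finite(r)) && all(r > 0))
  x <- mat[keep, , drop = FALSE]
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    r <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) r[i] <- x[i, j] / mean(x[i, ])
    out[j] <- median(r)
  }
  names(out) <- colnames(mat)
  out
}

# enumeration oracle for the two-sided Fisher test: walk every table with
# the observed margins, using factorial-based point probabilities
bruteFisherTwoSided <- function(a, b, cc, d) {
  m <- a + b; n <- cc + d; k <- a + cc
  support <- max(0, k - n):min(k, m)
  pt <- function(x) {
    exp(lfactorial(m) - lfactorial(x) - lfactorial(m - x) +
        lfactorial(n) - lfactorial(k - x) - lfactorial(n - k + x) +
        lfactorial(k) + lfactorial(m + n - k) - lfactorial(m + n))
  }
  probs <- vapply(support, pt, 1.0)
  obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# separable complete matrix: per-row abundance times per-channel loading
separableMatrix <- function(nrow, factors) {
  b <- rlnorm(nrow, 10, 1)
  m <- b %o% factors
  colnames(m) <- names(factors)
  m
}

# small fast simulation config for property tests
smallConfig <- function(seed, ...) {
  simulationConfig(nProteins = 400L, nTruePerBait = 15L, nNonspecific = 60L,
                   interactorPoolSize = 30L, nContaminants = 5L,
                   seed = as.integer(seed), ...)
}
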