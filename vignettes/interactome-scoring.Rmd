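---
title: "Scoring a bait interactome from 10-plex co-IP TMT data"
author: "coipTMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring a bait interactome from 10-plex co-IP TMT data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coipTMT)
```

## The experiment and the model

A multiplexed affinity-purification experiment immunoprecipitates a bait
protein from the same lysate with several antibody preparations, alongside
two kinds of controls: nonspecific-IgG pull-downs, which define the
bead-background proteome, and pull-downs of unrelated proteins, which gauge
specificity. Each eluate is labeled with one isobaric (TMT) reporter tag and
the ten channels are quantified together in one LC-MS/MS run. `coipTMT`
scores such an experiment in four stages.

**Channel QC and aggregation.** Labeling efficiency is the fraction of PSMs
carrying the label on the peptide N-terminus or a lysine
(`labelingEfficiency()`, gate 0.96). Channel loading is summarized by
median-of-ratio factors: for channel $c$,
$f_c = \mathrm{median}_i \left( x_{ic} / \bar x_{i\cdot} \right)$
over peptides $i$ quantified in every channel (`mixingCorrectionFactors()`),
and dividing by $f_c$ (`applyCorrection()`) equalizes loading. Peptides with
any missing channel are excluded from factor estimation because a
median-of-ratios is undefined on zeros; this is the one place the pipeline
uses complete rows only. The per-protein, per-channel *total signal* is
reporter intensity times ion injection time summed over the protein group's
PSMs (`proteinSignalFromPsms()`); injection-time units are taken as given,
the product being an arbitrary-unit signal.

**Enrichment.** Relative abundance is a protein's share of its channel's
total signal, $a_{pc} = S_{pc}/\sum_{p'} S_{p'c}$, computed after dropping
contaminant and decoy rows. The definition makes IP and control channels
comparable regardless of loading: multiplying a whole channel by any
constant changes nothing downstream (a property the tests assert). Fold
enrichment divides by the chemistry-matched IgG control:
$E_{ps} = a_{ps} / \max(a_{p,\mathrm{IgG}(s)}, \varepsilon)$. The floor
$\varepsilon$ keeps ratios finite when a protein is absent from the control;
the default is half the smallest nonzero abundance in that IgG channel,
which preserves ranking among affected proteins. Alternatives (`fixed`,
`drop`) are available where a fixed floor or exclusion is preferred.

**Cutoffs and assembly.** Ratios from all samples of one bead chemistry are
pooled and the empirical 95th percentile is that chemistry's cutoff
(`deriveCutoffs()`, the "top 5%" convention). Agarose and magnetic beads get
separate cutoffs because their background levels differ, which widens the
ratio distribution on the low-background chemistry. Quantiles use linear
interpolation between order statistics (`stats::quantile` type 7) so cutoffs
are bit-reproducible; at least 20 pooled values per group are required. A
protein enters a sample's enriched set when it is quantified by at least 3
peptides and its ratio strictly exceeds the cutoff (`enrichedSet()`). The
peptide filter guards against unreliable single-peptide ratios; the count
column used is whatever the input table provides (unique peptides by
default). The strict `>` comparison is the default, with a flag for `>=`,
since published threshold language varies between the two; the pooled
quantile is likewise computed after the peptide filter by default, with
`filterFirst = FALSE` available. The *interactome* is the union of enriched
sets over bait samples, and the *restricted background* the union over all
non-IgG samples (`assembleInteractome()`); the former is contained in the
latter by construction.

**Specificity.** Because pull-downs of two synaptic proteins share much of
their protein population, overlap statistics use the restricted background
as universe rather than the whole proteome. For each sample versus a
reference (by default the mixed-antibody agarose bait),
`pairwiseOverlapMatrix()` builds the 2x2 table on that universe and applies
a two-sided Fisher exact test. The two-sided p sums hypergeometric point
probabilities no larger than the observed table's (the convention of
standard exact-test implementations, documented here because doubling one
tail gives different values); point probabilities are evaluated in log
space, so universes of a few hundred proteins are numerically safe. The
odds ratio is the sample odds ratio $ad/bc$ with an infinity sentinel when
$bc = 0$, not the conditional MLE. Significance codes are `*`, `**`, `***`
at 0.05, 0.01, 0.001 on raw p-values; no multiplicity correction is applied
across the nine comparisons by default (matching how such matrices are
conventionally reported), with Benjamini-Hochberg behind a flag.
`annotationEnrichment()` applies the analogous one-sided tail test to
annotation sets intersected with the background.

## What the generator emulates

`simulateCoip()` plants ground truth in data with the statistical structure
the scoring assumes:

* **Layout.** `tenplexDesign()`: one IgG control per chemistry, four bait
  IPs (two per chemistry), four unrelated-control IPs.
* **Abundances.** Base abundances $\lambda_p$ are log-normal
  (`abundanceLogmean` $= \log 10^5$, `abundanceLogsd` $= 1$), a dynamic
  range of roughly two orders of magnitude typical of an IP eluate.
* **Planted interactors.** The four bait samples share one planted set of
  `nTruePerBait` = 40 proteins (they target the same bait); each unrelated
  sample gets its own 40. All five sets are drawn from a common
  "co-IP-prone" pool of 80 abundant proteins (`poolLogBoost` = 1), so an
  unrelated interactome overlaps the bait's at chance level *within the
  restricted background* - pull-downs of different synaptic proteins really
  do capture overlapping populations, and disjoint planted sets would make
  every bait-vs-unrelated comparison significantly *depleted* instead of
  null.
* **Specific capture.** In a channel whose planted set contains $p$, the
  signal multiplier is $B = 1 + (\rho - 1)/\beta_{chem}$ with $\rho$ =
  `bindingFoldTrue` = 6 and $\beta$ the chemistry background scale
  (agarose 1, magnetic 0.4). Antibody-driven capture does not scale with
  bead background, so on the low-background magnetic chemistry the same
  binding stands taller above its IgG control; this is what makes the
  derived magnetic cutoff roughly twice the agarose one, reproducing the
  characteristic cutoff asymmetry of the two chemistries.
* **Nonspecific binders.** 300 proteins carry `nonspecificFold` = 4 in
  *every* channel including the IgG controls, so their enrichment sits near
  1 and IgG normalization rejects them - the reason the controls exist.
* **Mixing.** Channels are combined at equal expected totals (the two-step
  equal-amount mixing), leaving a fixed residual per-channel imbalance of a
  few percent. Because planted signal inflates IP-channel totals, measured
  median-of-ratio factors on simulated data can drift a few percent beyond
  the residual imbalance itself; this compression is a real feature of
  composition-normalized data.
* **Noise.** Multiplicative log-normal noise with CV `noiseCv` = 0.2,
  typical of reporter-ion quantification after summing over spectra.
* **Peptide counts.** $k_p = 1 + \mathrm{Poisson}\big((\bar k - 1)\,
  \sigma(\gamma (\log D_p - d_{50}))\big)$, where $D_p$ is the protein's
  best loading-free channel abundance, $\bar k$ = `peptideMean` = 8,
  $\gamma$ = `detectShape` = 4 and $d_{50}$ sits `detectMid` = 1.2
  abundance-log-sds above the abundance log-mean. Identification in LC-MS/MS
  tracks abundance, so low-signal background proteins are the ones
  quantified by one or two peptides; this dependence is what gives the
  >=3-peptide filter its real-data meaning of removing unreliable
  low-signal ratios. With these defaults about a third of simulated
  proteins pass the filter (several hundred per channel pool) and roughly
  5% of pooled filter-passing ratio values carry planted signal, so the
  top-5% cutoff separates planted interactors from background - the regime
  the scoring method is built for.
* **PSM level.** Each protein/channel signal is split across
  $k_p \times$ `psmsPerPeptide` PSMs with exponential weights and uniform
  injection times in [10, 120] ms, so aggregation reproduces the recorded
  matrix exactly (a bookkeeping oracle the tests use); label flags are
  Bernoulli at `labelEfficiency` = 0.97.
* **Reproducibility.** All randomness comes from `seed` through R's
  Mersenne-Twister with inversion normals; the caller's RNG state is saved
  and restored.

What the generator does *not* emulate: missing channels within a quantified
protein, isotopic reporter impurity spillover, protein-inference ambiguity,
abundance-dependent (shot-noise) CV, or correlated peptide behavior.
Passing tests therefore demonstrate the scoring logic under the model's
assumptions, not robustness to those real-data pathologies.

## Numerical and design choices

* Quantile type 7, strict `>` threshold, and the half-minimum pseudocount
  are the defaults discussed above; all are surfaced as arguments.
* The mixing fixed point (apply factors, recompute, get 1) is exact - to
  floating point, and asserted at 1e-9 - when the matrix is separable into
  per-row abundance times per-channel loading, which is precisely the
  imbalance the correction targets. Under independent row-level noise a
  single correction step is only approximately idempotent.
* Degenerate inputs fail loudly and by name: duplicate channels, a missing
  or duplicated IgG control, an all-zero channel, no complete peptide rows,
  fewer than 20 pooled ratio values, set members outside the overlap
  universe.
* An empty interactome is representable end to end (empty member list in
  the JSON, recall 0, precision 1 by convention with an explicit flag).
* Exact one-sided annotation p-values are discrete and therefore
  conservative; the test suite checks calibration on their PIT-randomized
  counterpart, which is exactly uniform under the null, and checks the raw
  p-values for validity at the 5% level.

## Problem sizes used by the checks

The packaged checks run the default 2000-protein conditions for recovery
(planted precision/recall at seed 1 and overlap specificity over 100
seeds), a 12000-protein run for cutoff calibration (>= 10000 pooled ratio
values per chemistry), 500 x 10 matrices for the mixing fixed point, an
exhaustive enumeration of all 2x2 tables with N <= 40 for the exact test,
and 50 small scenarios for monotonicity properties. These sizes were chosen
to exercise each property at meaningful scale while keeping a full run in
the order of a minute.

## A worked run

```{r run}
run <- runPipeline(simConfig = simulationConfig(seed = 1L))
cutoffTheta(run$cutoffs)
vapply(enrichedSets(run$result), length, integer(1))
run$recovery
head(run$overlaps[, c("sample_b", "a", "b", "c", "d", "p", "code")])
```

The magnetic cutoff sits about twice the agarose cutoff; the interactome
recovers the 40 planted interactors; overlap with the other bait IPs is
highly significant while overlap with unrelated IPs is not - the pattern
that defines a specific interactome.

## Limitations

The scoring is only as good as the IgG controls: background not represented
in the matched control (e.g. chemistry lot effects) will not be normalized
away. Cutoffs derived from pooled quantiles are relative by construction -
they flag the top tail of the observed experiment, so an experiment with no
true binding still yields "enriched" sets of the expected 5% size; the
specificity stage, not the cutoff, is what distinguishes signal from such
noise. Proteins absent from both IP and control are invisible. Peptide
counts are taken from the input table; no protein inference is attempted.
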