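#' Build a simulation configuration
#'
#' Defaults describe a realistic 10-plex co-IP: ~2000 detectable protein
#' groups, a 40-protein planted interactome shared by the bait-antibody
#' channels, 40 planted interactors per unrelated-control channel (all drawn
#' from a common co-IP-prone pool, so unrelated interactomes overlap the
#' bait's at chance level within the restricted background), 300 nonspecific
#' binders elevated in every channel including the IgG controls, log-normal
#' base abundances, 20% multiplicative noise, mild channel loading imbalance,
#' and detectability-dependent peptide counts (see the vignette for the full
#' generative model and the rationale for each default).
#'
#' @param nProteins Total simulated protein groups.
#' @param nTruePerBait Planted interactors per antibody target.
#' @param nNonspecific Nonspecific binders (elevated in all channels).
#' @param nContaminants Contaminant rows (CON__ ids, flagged, abundant).
#' @param interactorPoolSize Size of the shared co-IP-prone pool the planted
#'   sets are drawn from.
#' @param bindingFoldTrue Specific-capture fold (rho) over the agarose
#'   background; on chemistry with background scale beta the bait-channel
#'   multiplier is \code{1 + (rho - 1) / beta} (specific capture does not
#'   scale with bead background, which is what makes magnetic ratios, and
#'   hence the magnetic cutoff, larger).
#' @param nonspecificFold Multiplier of nonspecific binders in all channels.
#' @param backgroundScale Named (agarose, magnetic) background level; the
#'   magnetic default is lower, as for epoxy magnetic beads.
#' @param abundanceLogmean,abundanceLogsd Log-normal base abundance.
#' @param poolLogBoost Log-abundance boost of pool/nonspecific proteins over
#'   plain background (co-IP-prone proteins are abundant ones).
#' @param noiseCv Coefficient of variation of multiplicative signal noise.
#' @param mixingFactors Per-channel loading factors (length 1 or one per
#'   channel); default a fixed mild imbalance pattern.
#' @param peptideMean Mean of (1 + peptide count) at full detectability.
#' @param detectMid Detectability midpoint, in abundance-log-sd units above
#'   the base log-mean.
#' @param detectShape Logistic steepness of detectability vs log signal.
#' @param psmsPerPeptide PSMs per peptide.
#' @param labelEfficiency Probability a PSM carries an isobaric label.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(nProteins = 2000L, nTruePerBait = 40L,
                             nNonspecific = 300L, nContaminants = 20L,
                             interactorPoolSize = 2L * nTruePerBait,
                             bindingFoldTrue = 6, nonspecificFold = 4,
                             backgroundScale = c(agarose = 1, magnetic = 0.4),
                             abundanceLogmean = log(1e5), abundanceLogsd = 1.0,
                             poolLogBoost = 1.0, noiseCv = 0.2,
                             mixingFactors = numeric(0),
                             peptideMean = 8, detectMid = 1.2,
                             detectShape = 4, psmsPerPeptide = 2L,
                             labelEfficiency = 0.97, seed = 1L) {
  new("SimulationConfig",
      nProteins = as.integer(nProteins), nTruePerBait = as.integer(nTruePerBait),
      nNonspecific = as.integer(nNonspecific),
      nContaminants = as.integer(nContaminants),
      interactorPoolSize = as.integer(interactorPoolSize),
      bindingFoldTrue = bindingFoldTrue, nonspecificFold = nonspecificFold,
      backgroundScale = backgroundScale,
      abundanceLogmean = abundanceLogmean, abundanceLogsd = abundanceLogsd,
      poolLogBoost = poolLogBoost, noiseCv = noiseCv,
      mixingFactors = mixingFactors,
      peptideMean = peptideMean, detectMid = detectMid,
      detectShape = detectShape, psmsPerPeptide = as.integer(psmsPerPeptide),
      labelEfficiency = labelEfficiency, seed = as.integer(seed))
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

.default_mixing <- function(n) {
  # fixed mild loading imbalance, recycled over channels
  base <- c(1.04, 0.97, 1.00, 0.94, 1.06, 0.99, 1.02, 0.96, 1.03, 0.98)
  rep_len(base, n)
}

#' Simulate a 10-plex co-IP TMT experiment with planted truth
#'
#' Generates a protein x channel total-signal matrix (and optionally the
#' underlying PSM table). Pre-mixing composition is
#' \eqn{\lambda_p \beta_{chem(c)} B_{p,c}} with
#' \eqn{B = 1 + (\rho - 1)/\beta} in a channel whose planted set contains p,
#' \eqn{B = } \code{nonspecificFold} for nonspecific binders in every
#' channel (IgG included), and \eqn{B = 1} otherwise. Channels are then
#' combined at equal expected total signal (emulating the wet-lab two-step
#' equal-amount mixing) up to the residual loading factors \eqn{m_c}, and
#' realized signal is the expectation times log-normal noise with the
#' configured CV. Peptide counts
#' are 1 + Poisson with rate \code{(peptideMean - 1)} times a logistic
#' function of the protein's best underlying (loading-free) channel
#' abundance. The PSM table splits each protein's channel signal across
#' peptides and PSMs with uniform injection times in [10, 120] ms, so that
#' intensity x injection time re-aggregates exactly to the signal matrix.
#' All randomness derives from \code{config@seed} (Mersenne-Twister); the
#' caller's RNG state is left untouched.
#'
#' @param config A [SimulationConfig-class].
#' @param design A [CoipDesign-class] (default [tenplexDesign()]).
#' @param psms Also generate the PSM table (default TRUE; protein-level-only
#'   runs are faster for simulation studies).
#' @return A list with \code{experiment} (a [CoipExperiment-class]),
#'   \code{truth} (a [GroundTruth-class]) and \code{psms} (data.frame or
#'   NULL).
#' @export
simulateCoip <- function(config, design = tenplexDesign(), psms = TRUE) {
  stopifnot(is(config, "SimulationConfig"), is(design, "CoipDesign"))
  ch <- designTable(design)
  n_ch <- nrow(ch)
  n_targets <- length(nonIggSamples(design))
  if (config@nTruePerBait > 0L &&
      config@interactorPoolSize + config@nNonspecific > config@nProteins)
    stop("infeasible config: interactor pool plus nonspecific binders exceed nProteins")
  .with_seed(config@seed, {
    ids <- sprintf("P%05d", seq_len(config@nProteins))

    # --- planted structure ------------------------------------------------
    pool <- if (config@nTruePerBait > 0L) sample(ids, config@interactorPoolSize)
            else character(0)
    non_igg <- ch[ch$role != "igg_control", , drop = FALSE]
    # bait channels share one planted set (same antibody target); each
    # unrelated control gets its own draw from the shared pool
    bait_set <- if (config@nTruePerBait > 0L) sample(pool, config@nTruePerBait)
                else character(0)
    true_sets <- lapply(seq_len(nrow(non_igg)), function(i) {
      if (config@nTruePerBait == 0L) return(character(0))
      if (non_igg$role[i] == "bait") bait_set
      else sample(pool, config@nTruePerBait)
    })
    names(true_sets) <- non_igg$sample_name
    nonspecific <- sample(setdiff(ids, pool), config@nNonspecific)

    # --- abundances and binding multipliers -------------------------------
    lambda <- stats::setNames(
      stats::rlnorm(config@nProteins, config@abundanceLogmean, config@abundanceLogsd),
      ids)
    boost <- exp(config@poolLogBoost)
    lambda[pool] <- lambda[pool] * boost
    lambda[nonspecific] <- lambda[nonspecific] * boost

    beta <- config@backgroundScale[ch$chemistry]
    m <- if (length(config@mixingFactors)) rep_len(config@mixingFactors, n_ch)
         else .default_mixing(n_ch)

    B <- matrix(1, config@nProteins, n_ch, dimnames = list(ids, ch$channel_id))
    B[nonspecific, ] <- config@nonspecificFold
    rho <- config@bindingFoldTrue
    for (i in seq_len(nrow(non_igg))) {
      cid <- non_igg$channel_id[i]
      bchem <- config@backgroundScale[[non_igg$chemistry[i]]]
      B[true_sets[[non_igg$sample_name[i]]], cid] <- 1 + (rho - 1) / bchem
    }

    # Equal-amount mixing: channels are combined at equal expected total
    # signal (the two-step wet-lab mixing), so the bead-background scale
    # beta acts only through the binding multipliers B; the residual
    # per-channel loading imbalance m survives mixing.
    raw <- lambda * B * rep(beta, each = config@nProteins)
    tot <- colSums(raw)
    mu <- raw * rep(mean(tot) / tot * m, each = config@nProteins)
    dimnames(mu) <- list(ids, ch$channel_id)

    # --- noise ------------------------------------------------------------
    if (config@noiseCv > 0) {
      sdlog <- sqrt(log(1 + config@noiseCv^2))
      noise <- matrix(stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog),
                      nrow(mu), ncol(mu))
      sig <- mu * noise
    } else sig <- mu

    # --- detectability-dependent peptide counts ---------------------------
    detect <- lambda * apply(B, 1L, max)   # best loading-free channel abundance
    mid <- config@abundanceLogmean + config@detectMid * config@abundanceLogsd
    frac <- stats::plogis(config@detectShape * (log(detect) - mid))
    npep <- 1L + stats::rpois(config@nProteins, (config@peptideMean - 1) * frac)

    # --- contaminants -----------------------------------------------------
    if (config@nContaminants > 0L) {
      cid <- sprintf("CON__C%03d", seq_len(config@nContaminants))
      clam <- stats::rlnorm(config@nContaminants,
                            config@abundanceLogmean + config@poolLogBoost,
                            config@abundanceLogsd / 2)
      cmu <- clam %o% m
      if (config@noiseCv > 0) {
        sdlog <- sqrt(log(1 + config@noiseCv^2))
        cmu <- cmu * matrix(stats::rlnorm(length(cmu), -sdlog^2 / 2, sdlog),
                            nrow(cmu), ncol(cmu))
      }
      rownames(cmu) <- cid
      colnames(cmu) <- ch$channel_id
      cpep <- 1L + stats::rpois(config@nContaminants, config@peptideMean - 1)
      sig <- rbind(sig, cmu)
      npep_all <- c(npep, cpep)
      contam <- c(rep(FALSE, config@nProteins), rep(TRUE, config@nContaminants))
    } else {
      npep_all <- npep
      contam <- rep(FALSE, config@nProteins)
    }

    experiment <- CoipExperiment(sig, design, nPeptides = npep_all,
                                 isContaminant = contam,
                                 isDecoy = logical(nrow(sig)))
    truth <- new("GroundTruth", trueInteractors = true_sets,
                 nonspecific = nonspecific, lambda = lambda,
                 peptides = stats::setNames(as.integer(npep), ids),
                 expectedSignal = mu)
    psm_tab <- if (psms) .psms_from_signal(sig, npep_all, config, design) else NULL
    list(experiment = experiment, truth = truth, psms = psm_tab)
  })
}

# Split a protein x channel signal matrix into a PSM table such that
# sum(intensity * injection_time) per protein/channel reproduces the matrix.
.psms_from_signal <- function(sig, npep, config, design) {
  ids <- rownames(sig)
  n_psm_per <- npep * config@psmsPerPeptide
  total <- sum(n_psm_per)
  prot <- rep(ids, n_psm_per)
  pep <- unlist(lapply(seq_along(ids), function(i)
    rep(sprintf("%s_pep%02d", ids[i], seq_len(npep[i])),
        each = config@psmsPerPeptide)), use.names = FALSE)
  it <- stats::runif(total, 10, 120)
  # exponential split weights, normalized within protein
  w <- stats::rexp(total)
  wsum <- rowsum(w, prot)[ids, ]
  w <- w / rep(wsum, n_psm_per)
  share <- sig[prot, , drop = FALSE] * w
  intensity <- share / it
  colnames(intensity) <- paste0("intensity.", colnames(sig))
  nterm <- stats::runif(total) < config@labelEfficiency
  lys <- stats::runif(total) < 0.4
  data.frame(psm_id = sprintf("psm%07d", seq_len(total)),
             protein_id = prot, peptide_sequence = pep,
             injection_time = it,
             has_nterm_label = nterm, has_lysine_label = lys,
             as.data.frame(intensity, optional = TRUE, check.names = FALSE),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write the simulated tables to disk
#'
#' Emits the exact dialects the readers consume: a protein-group TSV
#' (\code{proteinGroups.tsv}), a PSM TSV (\code{psms.tsv}, if present), the
#' design YAML (\code{design.yaml}) and a ground-truth JSON
#' (\code{truth.json}).
#'
#' @param sim A list from [simulateCoip()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
writeSimulatedTables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- sim$experiment
  sig <- assay(x, "signal")
  rd <- rowData(x)
  tab <- data.frame(protein_id = rownames(sig),
                    gene_symbol = rd$gene_symbol,
                    n_peptides = rd$n_peptides,
                    is_contaminant = ifelse(rd$is_contaminant, "+", ""),
                    is_decoy = ifelse(rd$is_decoy, "+", ""),
                    stringsAsFactors = FALSE, check.names = FALSE)
  sigdf <- as.data.frame(sig, optional = TRUE, check.names = FALSE)
  colnames(sigdf) <- paste("signal", colnames(sig))
  tab <- cbind(tab, sigdf)
  pg <- file.path(dir, "proteinGroups.tsv")
  utils::write.table(tab, pg, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(protein_groups = pg)
  if (!is.null(sim$psms)) {
    ps <- file.path(dir, "psms.tsv")
    psm <- sim$psms
    psm$has_nterm_label <- ifelse(psm$has_nterm_label, "+", "")
    psm$has_lysine_label <- ifelse(psm$has_lysine_label, "+", "")
    utils::write.table(psm, ps, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["psms"] <- ps
  }
  dy <- file.path(dir, "design.yaml")
  writeDesign(coipDesign(sim$experiment), dy)
  paths["design"] <- dy
  tj <- file.path(dir, "truth.json")
  truth <- sim$truth
  writeLines(jsonlite::toJSON(list(
    true_interactors = lapply(truth@trueInteractors, as.list),
    nonspecific = as.list(truth@nonspecific)),
    auto_unbox = TRUE), tj)
  paths["truth"] <- tj
  invisible(paths)
}

#' Score pipeline output against the planted truth
#'
#' The positive class T is the union of planted interactor sets over the
#' design's bait samples; nonspecific binders and all other proteins count
#' as negatives. Precision of an empty interactome is 1 by convention and
#' flagged.
#'
#' @param result An [InteractomeResult-class].
#' @param truth A [GroundTruth-class] from the same simulated experiment.
#' @param design The [CoipDesign-class] (defaults to the result's design).
#' @return A [RecoveryMetrics-class].
#' @export
scoreRecovery <- function(result, truth, design = coipDesign(result)) {
  stopifnot(is(result, "InteractomeResult"), is(truth, "GroundTruth"))
  baits <- baitSamples(design)
  miss <- setdiff(baits, names(truth@trueInteractors))
  if (length(miss))
    stop("truth has no planted sets for bait sample(s): ",
         paste(miss, collapse = ", "))
  tset <- unique(unlist(truth@trueInteractors[baits], use.names = FALSE))
  ihat <- interactome(result)
  tp <- intersect(ihat, tset)
  empty <- length(ihat) == 0L
  precision <- if (empty) 1 else length(tp) / length(ihat)
  recall <- if (length(tset)) length(tp) / length(tset) else NA_real_
  f1 <- if (!is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  new("RecoveryMetrics", precision = precision, recall = recall, f1 = f1,
      falsePositives = setdiff(ihat, tset),
      falseNegatives = setdiff(tset, ihat),
      emptyInteractome = empty)
}
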