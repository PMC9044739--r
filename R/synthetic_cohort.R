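#' Simulation configuration for a synthetic serum cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator: a
#' prostatectomy-style cohort with a binary biochemical-recurrence outcome,
#' log-normal serum protein abundances measured at the transition level,
#' per-sample batch factors removable by a bovine A1AG spike-in, and
#' abundance-dependent (MNAR) plus completely-random (MCAR) missingness.
#' A configurable number of "informative" proteins is planted whose
#' abundance is *lower* in patients who recur, mirroring extracellular
#' matrix markers whose serum levels fall with disease aggressiveness.
#'
#' @param n_patients number of patients.
#' @param n_proteins number of candidate proteins (excluding the spike-in
#'   reference).
#' @param n_informative number of planted informative proteins.
#' @param effect_log2 mean log2 shift of the informative proteins between
#'   the non-recurrence and recurrence groups; positive values mean lower
#'   abundance in recurrence patients.
#' @param recurrence_rate probability of biochemical recurrence.
#' @param peptides_per_protein peptides monitored per protein.
#' @param transitions_per_precursor transitions per precursor (4 or more is
#'   typical for PRM roll-ups).
#' @param batch_sigma sd of the per-sample log2 processing (batch) factor.
#' @param noise_sigma sd of the per-measurement log2 residual.
#' @param mnar_quantile abundance quantile of each protein below which a
#'   measurement becomes eligible for intensity-dependent censoring.
#' @param mnar_prob censoring probability for MNAR-eligible measurements.
#' @param mcar_prob independent completely-at-random dropout probability.
#' @param followup_max_months follow-up horizon in months.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 78,
                       n_proteins = 21,
                       n_informative = 2,
                       effect_log2 = 1,
                       recurrence_rate = 0.4,
                       peptides_per_protein = 2,
                       transitions_per_precursor = 5,
                       batch_sigma = 0.5,
                       noise_sigma = 0.5,
                       mnar_quantile = 0.2,
                       mnar_prob = 0.5,
                       mcar_prob = 0.02,
                       followup_max_months = 36,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_proteins = as.integer(n_proteins),
    n_informative = as.integer(n_informative),
    effect_log2 = effect_log2,
    recurrence_rate = recurrence_rate,
    peptides_per_protein = as.integer(peptides_per_protein),
    transitions_per_precursor = as.integer(transitions_per_precursor),
    batch_sigma = batch_sigma,
    noise_sigma = noise_sigma,
    mnar_quantile = mnar_quantile,
    mnar_prob = mnar_prob,
    mcar_prob = mcar_prob,
    followup_max_months = followup_max_months,
    seed = as.integer(seed)
  )
  probs <- c("recurrence_rate", "mnar_quantile", "mnar_prob", "mcar_prob")
  for (p in probs) {
    if (!is_number(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stopf("'%s' must be a probability in [0, 1]", p)
  }
  if (cfg$n_informative > cfg$n_proteins)
    stopf("n_informative (%d) exceeds n_proteins (%d)",
          cfg$n_informative, cfg$n_proteins)
  if (!is_number(cfg$effect_log2))
    stopf("'effect_log2' must be a finite number")
  if (cfg$n_patients < 2L) stopf("need at least 2 patients")
  if (cfg$batch_sigma < 0 || cfg$noise_sigma < 0)
    stopf("sigmas must be non-negative")
  if (cfg$followup_max_months <= 0)
    stopf("'followup_max_months' must be positive")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d patients, %d proteins (%d informative, effect %.2f log2)\n",
    x$n_patients, x$n_proteins, x$n_informative, x$effect_log2))
  cat(sprintf("  recurrence rate %.2f, batch sd %.2f, noise sd %.2f, seed %d\n",
              x$recurrence_rate, x$batch_sigma, x$noise_sigma, x$seed))
  invisible(x)
}

# Deterministic NCCN-style category from PSA, biopsy Gleason and a stage
# proxy, following the low/high composite rule: low grade needs confined
# stage and Gleason <= 6; points accumulate with Gleason 7, Gleason >= 8,
# and extraprostatic stage, capped at category 4.
derive_nccn <- function(psa, gleason, stage_pt3) {
  pmin(4L, 1L + (gleason >= 7L) + (gleason >= 8L) + as.integer(stage_pt3))
}

#' Simulate a prostatectomy cohort with recurrence follow-up
#'
#' Draws patient-level clinical covariates and the binary
#' biochemical-recurrence outcome. Pre-operative PSA lies in the 2-10
#' ng/ml inclusion window, biopsy Gleason scores span 6-10 with more
#' aggressive grades enriched among recurrence cases, and an NCCN-style
#' category in 1-4 is derived deterministically from PSA, Gleason, and a
#' latent stage proxy. Event times for recurrence cases are exponential,
#' truncated to the follow-up horizon; non-recurrence patients are censored
#' at a uniform time.
#'
#' @param config a [sim_config()].
#' @return a list with `patients` (data.frame: `sample_id`, `psa_ng_ml`,
#'   `gleason_bx`, `nccn`, `recurrence_event`, `followup_months`) and
#'   `truth` (informative protein ids, latent risk, batch factors filled in
#'   by [simulate_transition_report()]).
#' @export
simulate_patients <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "patients"), {
    n <- config$n_patients
    event <- stats::rbinom(n, 1L, config$recurrence_rate) == 1L
    if (config$recurrence_rate > 0 && config$recurrence_rate < 1 &&
        (sum(event) < 2L || sum(!event) < 2L))
      stopf("degenerate cohort: fewer than 2 patients in one outcome group (n=%d, rate=%.3f)",
            n, config$recurrence_rate)

    # latent aggressiveness drives Gleason/PSA so the clinical baseline has
    # moderate (not perfect) predictive value, as in real cohorts
    risk <- stats::rnorm(n, mean = ifelse(event, 0.8, -0.4), sd = 1)
    psa <- pmin(10, pmax(2, 6 + 1.2 * risk + stats::rnorm(n, 0, 1.6)))
    gleason <- vapply(risk, function(r) {
      w <- c(0.45, 0.33, 0.14, 0.06, 0.02) * exp(0.8 * r * (0:4))
      sample(6:10, 1L, prob = w / sum(w))
    }, integer(1))
    stage_pt3 <- stats::runif(n) < stats::plogis(-1 + 1.1 * risk)
    nccn <- derive_nccn(psa, gleason, stage_pt3)

    horizon <- config$followup_max_months
    # truncated exponential via inverse CDF so every event precedes horizon
    rate <- 3 / horizon
    u <- stats::runif(n)
    t_event <- -log(1 - u * (1 - exp(-rate * horizon))) / rate
    t_cens <- stats::runif(n, 0, horizon)
    followup <- ifelse(event, t_event, t_cens)

    patients <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      psa_ng_ml = psa,
      gleason_bx = gleason,
      nccn = nccn,
      recurrence_event = event,
      followup_months = followup,
      stringsAsFactors = FALSE
    )
    protein_ids <- sprintf("PROT%02d", seq_len(config$n_proteins))
    truth <- list(
      informative_protein_ids = protein_ids[seq_len(config$n_informative)],
      protein_ids = protein_ids,
      latent_risk = stats::setNames(risk, patients$sample_id),
      group = stats::setNames(event, patients$sample_id),
      batch_factors = NULL
    )
    list(patients = patients, truth = truth)
  })
}

#' Simulate a transition-level PRM report for a cohort
#'
#' Generates the delimited transition report the quantitation stage
#' consumes: for every sample and protein, `peptides_per_protein` peptides
#' each with `transitions_per_precursor` transitions, with log-normal
#' abundances, fixed per-peptide and per-transition response weights, a
#' shared per-sample batch factor, and measurement noise. The bovine A1AG
#' spike-in reference (`A1AG_BOVIN`) is present and complete in every
#' sample with abundance proportional to the sample's batch factor, so
#' dividing by it removes the batch factor exactly when `noise_sigma = 0`.
#' Informative proteins have their log2 mean lowered by `effect_log2` in
#' recurrence patients. Whole protein-sample measurements are censored
#' MNAR (if the pre-noise abundance falls below the protein's
#' `mnar_quantile`, with probability `mnar_prob`) or MCAR (`mcar_prob`);
#' the reference is never censored.
#'
#' @param config a [sim_config()].
#' @param patients patient table from [simulate_patients()].
#' @param truth truth sidecar from [simulate_patients()].
#' @return list with `transitions` (data.frame: `sample_id`, `protein`,
#'   `peptide`, `precursor_charge`, `transition_id`, `area`) and the
#'   `truth` sidecar completed with per-sample batch factors.
#' @export
simulate_transition_report <- function(config, patients, truth) {
  stopifnot(inherits(config, "sim_config"), nrow(patients) >= 1L)
  with_seed(derive_seed(config$seed, "transitions"), {
    n <- nrow(patients)
    prot <- truth$protein_ids
    np <- length(prot)
    ppp <- config$peptides_per_protein
    tpp <- config$transitions_per_precursor

    base_log2 <- stats::setNames(stats::runif(np, 14, 20), prot)
    # fixed instrument response per peptide / transition (sample-invariant)
    pep_w <- matrix(2^stats::rnorm(np * ppp, 0, 0.8), np, ppp,
                    dimnames = list(prot, NULL))
    trans_w <- array(2^stats::rnorm(np * ppp * tpp, 0, 0.6),
                     dim = c(np, ppp, tpp))
    batch <- stats::setNames(2^stats::rnorm(n, 0, config$batch_sigma),
                             patients$sample_id)

    shift <- matrix(0, n, np, dimnames = list(patients$sample_id, prot))
    inf <- truth$informative_protein_ids
    shift[patients$recurrence_event, inf] <- -config$effect_log2

    # per-sample per-protein true (batch-free) log2 abundance; the same
    # noise_sigma drives the sample-level residual and the per-transition
    # residual so noise_sigma = 0 silences every variance source at once
    bio_noise <- matrix(stats::rnorm(n * np, 0, config$noise_sigma), n, np)
    log2_abund <- matrix(base_log2, n, np, byrow = TRUE) + shift + bio_noise

    # MNAR eligibility from the protein-wise abundance quantile (pre-noise)
    censored <- matrix(FALSE, n, np)
    if (config$mnar_prob > 0 && config$mnar_quantile > 0) {
      for (j in seq_len(np)) {
        thr <- stats::quantile(log2_abund[, j], config$mnar_quantile,
                               names = FALSE, type = 7)
        eligible <- log2_abund[, j] <= thr
        censored[, j] <- eligible & (stats::runif(n) < config$mnar_prob)
      }
    }
    if (config$mcar_prob > 0)
      censored <- censored | (matrix(stats::runif(n * np), n, np) <
                                config$mcar_prob)

    keep <- which(!censored, arr.ind = TRUE)
    nk <- nrow(keep)
    per <- ppp * tpp
    i_vec <- rep(keep[, 1], each = per)
    j_vec <- rep(keep[, 2], each = per)
    p_vec <- rep(rep(seq_len(ppp), each = tpp), times = nk)
    t_vec <- rep(seq_len(tpp), times = nk * ppp)
    abund <- 2^log2_abund[cbind(i_vec, j_vec)] * batch[i_vec]
    w <- pep_w[cbind(j_vec, p_vec)] * trans_w[cbind(j_vec, p_vec, t_vec)]
    noise <- 2^stats::rnorm(nk * per, 0, config$noise_sigma)
    target <- data.frame(
      sample_id = patients$sample_id[i_vec],
      protein = prot[j_vec],
      peptide = sprintf("%s_PEP%d", prot[j_vec], p_vec),
      precursor_charge = rep(2L, length(i_vec)),
      transition_id = sprintf("y%d", t_vec + 3L),
      area = abund * w * noise,
      stringsAsFactors = FALSE
    )
    # spike-in reference: abundance tracks the batch factor exactly and is
    # never censored (it is the normalizer)
    ref_level <- 2^16
    ri <- rep(seq_len(n), each = tpp)
    rt <- rep(seq_len(tpp), times = n)
    ref_noise <- 2^stats::rnorm(n * tpp, 0, config$noise_sigma)
    reference <- data.frame(
      sample_id = patients$sample_id[ri],
      protein = "A1AG_BOVIN",
      peptide = "A1AG_BOVIN_PEP1",
      precursor_charge = 2L,
      transition_id = sprintf("y%d", rt + 3L),
      area = ref_level * batch[ri] *
        2^seq(0, -1, length.out = tpp)[rt] * ref_noise,
      stringsAsFactors = FALSE
    )
    transitions <- rbind(target, reference)
    truth$batch_factors <- batch
    list(transitions = transitions, truth = truth)
  })
}

#' Simulate a full cohort (patients plus transition report)
#'
#' Convenience wrapper chaining [simulate_patients()] and
#' [simulate_transition_report()].
#'
#' @param config a [sim_config()].
#' @return list with `patients`, `transitions`, `truth`.
#' @export
simulate_cohort <- function(config) {
  pt <- simulate_patients(config)
  tr <- simulate_transition_report(config, pt$patients, pt$truth)
  list(patients = pt$patients, transitions = tr$transitions,
       truth = tr$truth)
}
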