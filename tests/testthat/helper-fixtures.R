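# Shared in-code fixtures for the suite. Everything is generated at test
# time; nothing is read from disk.

# A small, fast cohort for unit tests of the quantitation and search path.
tiny_cohort <- function(seed = 11, n_patients = 40, n_proteins = 6,
                        effect_log2 = 1.5, ...) {
  simulate_cohort(sim_config(n_patients = n_patients,
                             n_proteins = n_proteins,
                             effect_log2 = effect_log2, seed = seed, ...))
}

# Quantity table + patients ready for model evaluation.
tiny_quantified <- function(seed = 11, ...) {
  cohort <- tiny_cohort(seed = seed, ...)
  qt <- normalize_to_reference(quantify_proteins(cohort$transitions))
  list(table = qt, patients = cohort$patients, truth = cohort$truth)
}

# Pure-noise feature matrix + patient table with labels independent of
# every feature — the null configuration for calibration checks.
null_cohort <- function(seed, n = 100, p = 3) {
  set.seed(seed)
  mat <- matrix(2^rnorm(n * p, 15, 1), n, p,
                dimnames = list(sprintf("S%03d", 1:n),
                                sprintf("NOISE%02d", 1:p)))
  patients <- data.frame(
    sample_id = rownames(mat),
    psa_ng_ml = runif(n, 2, 10),
    gleason_bx = sample(6:10, n, replace = TRUE),
    recurrence_event = rbinom(n, 1, 0.4) == 1,
    stringsAsFactors = FALSE)
  # guarantee both classes
  if (sum(patients$recurrence_event) < 2)
    patients$recurrence_event[1:2] <- TRUE
  if (sum(!patients$recurrence_event) < 2)
    patients$recurrence_event[3:4] <- FALSE
  list(table = mat, patients = patients)
}

# Brute-force AUC oracle: concordant/discordant pair counting, ties half.
auc_pair_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# One planted-recovery experiment at the scaled study conditions: 200
# patients, 12 proteins (2 informative, 1 log2 effect), exhaustive search
# to 3-plex panels, 20 paired bootstrap folds, 100-tree forests.
recovery_run <- function(seed) {
  cfg <- sim_config(n_patients = 200, n_proteins = 12, n_informative = 2,
                    effect_log2 = 1, seed = seed)
  cohort <- simulate_cohort(cfg)
  qt <- normalize_to_reference(quantify_proteins(cohort$transitions))
  pp <- preprocess_table(qt, preprocess_config(imputation_seed = seed))
  models <- enumerate_models(candidate_proteins(pp$table), 3L, "psa")
  plan <- make_bootstrap_plan(nrow(cohort$patients),
                              cohort$patients$recurrence_event, 20L, seed)
  res <- search_panels(models, pp$table, cohort$patients, plan, 100L)
  eq <- rank_and_equivalence(res)
  prev <- feature_prevalence(eq)
  list(top2 = utils::head(prev$feature, 2),
       planted = cohort$truth$informative_protein_ids,
       equivalence_size = length(eq$members))
}
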