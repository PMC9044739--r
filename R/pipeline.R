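#' Assemble a full pipeline run configuration
#'
#' One declarative object drives a whole run: the synthetic-cohort
#' settings, preprocessing thresholds, search parameters, and final-model
#' settings. A single global `seed` deterministically derives every
#' stage's own seed, so one seed fixes the entire run.
#'
#' @param outdir output directory for stage tables and the manifest.
#' @param seed global integer seed.
#' @param sim named list of [sim_config()] overrides.
#' @param preprocess named list of [preprocess_config()] overrides.
#' @param search list: `k_max`, `n_folds`, `n_trees`, `alpha`,
#'   `base_features`.
#' @param fit list: `n_markers` (panel size taken from the top of the
#'   prevalence table), `base`, `n_trees`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = list(),
                            preprocess = list(),
                            search = list(), fit = list()) {
  search_def <- list(k_max = 3L, n_folds = 20L, n_trees = 100L,
                     alpha = 0.05, base_features = "psa")
  fit_def <- list(n_markers = 2L, base = c("psa", "gleason"),
                  n_trees = 200L)
  cfg <- list(outdir = outdir, seed = as.integer(seed), sim = sim,
              preprocess = preprocess,
              search = utils::modifyList(search_def, search),
              fit = utils::modifyList(fit_def, fit))
  structure(cfg, class = "pipeline_config")
}

pipeline_stages <- c("simulate", "quantify", "preprocess", "search",
                     "fit", "evaluate")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

read_patients <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$recurrence_event <- as.logical(df$recurrence_event)
  df
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in the fixed order
#' simulate -> quantify -> preprocess -> search -> fit -> evaluate,
#' writing each stage's tables under `config$outdir` and returning a run
#' manifest (configuration echo, per-stage outputs with content digests,
#' and headline numbers). Running a stage whose input was produced
#' neither earlier in this run nor by a previous run in the same
#' directory is an error.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (default: all, in order).
#' @return the run manifest (list), invisibly written to
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  if (is.unsorted(match(stages, pipeline_stages)))
    stopf("stages must be requested in pipeline order (%s)",
          paste(pipeline_stages, collapse = " -> "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$outdir, f)
  outputs <- character(0)
  summary <- list()
  env <- new.env(parent = emptyenv())

  need <- function(obj, file, reader, stage) {
    if (!is.null(env[[obj]])) return(env[[obj]])
    if (!file.exists(path(file)))
      stopf("stage '%s' needs '%s'; run the producing stage first",
            stage, file)
    env[[obj]] <- reader(path(file))
    env[[obj]]
  }

  if ("simulate" %in% stages) {
    scfg <- do.call(sim_config,
                    utils::modifyList(list(seed = derive_seed(config$seed,
                                                              "simulate")),
                                      config$sim))
    cohort <- simulate_cohort(scfg)
    env$patients <- cohort$patients
    env$transitions <- cohort$transitions
    env$truth <- cohort$truth
    write_tsv(cohort$patients, path("patients.tsv"))
    write_tsv(cohort$transitions, path("transitions.tsv"))
    jsonlite::write_json(
      list(informative_protein_ids = cohort$truth$informative_protein_ids,
           batch_factors = as.list(cohort$truth$batch_factors),
           latent_risk = as.list(cohort$truth$latent_risk)),
      path("truth.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "patients.tsv", "transitions.tsv", "truth.json")
    summary$n_patients <- nrow(cohort$patients)
    summary$n_events <- sum(cohort$patients$recurrence_event)
  }

  if ("quantify" %in% stages) {
    tr <- need("transitions", "transitions.tsv",
               function(p) utils::read.delim(p, stringsAsFactors = FALSE),
               "quantify")
    qt <- quantify_proteins(tr)
    qt <- normalize_to_reference(qt)
    env$quant <- qt
    write_quant_table(qt, path("protein_matrix.tsv"))
    outputs <- c(outputs, "protein_matrix.tsv")
    summary$n_proteins_quantified <- length(candidate_proteins(qt))
  }

  if ("preprocess" %in% stages) {
    qt <- need("quant", "protein_matrix.tsv",
               function(p) read_quant_table(p, normalizer_id = "A1AG_BOVIN"),
               "preprocess")
    pcfg <- do.call(preprocess_config,
                    utils::modifyList(
                      list(imputation_seed = derive_seed(config$seed,
                                                         "impute")),
                      config$preprocess))
    pp <- preprocess_table(qt, pcfg)
    env$completed <- pp$table
    write_quant_table(pp$table, path("protein_matrix_completed.tsv"))
    qc <- data.frame(protein = names(pp$presence),
                     presence_fraction = as.numeric(pp$presence),
                     stringsAsFactors = FALSE)
    write_tsv(qc, path("qc_presence.tsv"))
    write_tsv(pp$flagged, path("qc_outliers.tsv"))
    outputs <- c(outputs, "protein_matrix_completed.tsv",
                 "qc_presence.tsv", "qc_outliers.tsv")
    summary$n_proteins_kept <- length(candidate_proteins(pp$table))
    summary$n_outliers_flagged <- nrow(pp$flagged)
  }

  if ("search" %in% stages) {
    qt <- need("completed", "protein_matrix_completed.tsv",
               function(p) read_quant_table(p, normalizer_id = "A1AG_BOVIN"),
               "search")
    patients <- need("patients", "patients.tsv", read_patients, "search")
    sc <- config$search
    models <- enumerate_models(candidate_proteins(qt), sc$k_max,
                               sc$base_features)
    plan <- make_bootstrap_plan(nrow(patients), patients$recurrence_event,
                                sc$n_folds,
                                derive_seed(config$seed, "plan"))
    results <- search_panels(models, qt, patients, plan, sc$n_trees)
    eq <- rank_and_equivalence(results, sc$alpha)
    prev <- feature_prevalence(eq)
    env$equivalence <- eq
    env$prevalence <- prev
    ranking <- data.frame(
      rank = seq_along(eq$ranked),
      model = vapply(eq$ranked, function(r) r$model$label, character(1)),
      median_auc = vapply(eq$ranked, `[[`, numeric(1), "median_auc"),
      mean_auc = vapply(eq$ranked, `[[`, numeric(1), "mean_auc"),
      sd_auc = vapply(eq$ranked, `[[`, numeric(1), "sd_auc"),
      adjusted_p = eq$adjusted_p,
      in_equivalence_set = seq_along(eq$ranked) %in% eq$member_idx,
      stringsAsFactors = FALSE)
    write_tsv(ranking, path("ranking.tsv"))
    write_tsv(prev, path("prevalence.tsv"))
    outputs <- c(outputs, "ranking.tsv", "prevalence.tsv")
    summary$n_models <- length(models)
    summary$equivalence_set_size <- length(eq$members)
    summary$best_model <- eq$ranked[[1]]$model$label
    summary$best_median_auc <- eq$ranked[[1]]$median_auc
    summary$top_features <- utils::head(prev$feature, 5)
  }

  if ("fit" %in% stages) {
    qt <- need("completed", "protein_matrix_completed.tsv",
               function(p) read_quant_table(p, normalizer_id = "A1AG_BOVIN"),
               "fit")
    patients <- need("patients", "patients.tsv", read_patients, "fit")
    prev <- if (!is.null(env$prevalence)) env$prevalence
    else {
      if (!file.exists(path("prevalence.tsv")))
        stopf("stage 'fit' needs 'prevalence.tsv'; run 'search' first")
      utils::read.delim(path("prevalence.tsv"), stringsAsFactors = FALSE)
    }
    markers <- utils::head(prev$feature, config$fit$n_markers)
    model <- fit_final(qt, patients, markers, config$fit$base,
                       config$fit$n_trees,
                       seed = derive_seed(config$seed, "fit"))
    env$risk_model <- model
    strat <- stratify(model, qt, patients)
    env$stratification <- strat
    st <- data.frame(sample_id = patients$sample_id,
                     score = as.numeric(strat$scores),
                     risk_group = as.character(strat$risk_group),
                     stringsAsFactors = FALSE)
    write_tsv(st, path("stratification.tsv"))
    outputs <- c(outputs, "stratification.tsv")
    summary$final_markers <- markers
    summary$cutoff <- model$cutoff
    summary$n_low <- strat$n_low
    summary$n_high <- strat$n_high
  }

  if ("evaluate" %in% stages) {
    patients <- need("patients", "patients.tsv", read_patients, "evaluate")
    strat <- if (!is.null(env$stratification)) {
      list(scores = env$stratification$scores,
           group = env$stratification$risk_group)
    } else {
      if (!file.exists(path("stratification.tsv")))
        stopf("stage 'evaluate' needs 'stratification.tsv'; run 'fit' first")
      st <- utils::read.delim(path("stratification.tsv"),
                              stringsAsFactors = FALSE)
      list(scores = stats::setNames(st$score, st$sample_id),
           group = factor(st$risk_group, levels = c("low", "high")))
    }
    y <- patients$recurrence_event
    est <- auc_estimate(strat$scores, y)
    dl <- delong_test(strat$scores, patients$psa_ng_ml, y)
    km <- km_estimate(patients$followup_months, y, strat$group)
    lrt <- lrt_two_groups(patients$followup_months, y, strat$group)
    evaldf <- data.frame(
      quantity = c("panel_auc", "panel_auc_ci_low", "panel_auc_ci_high",
                   "psa_auc", "delong_p_vs_psa", "lrt_statistic",
                   "lrt_p"),
      value = c(est$auc, est$ci_low, est$ci_high, dl$auc_b, dl$p_value,
                lrt$statistic, lrt$p_value),
      stringsAsFactors = FALSE)
    write_tsv(evaldf, path("evaluation.tsv"))
    kmdf <- do.call(rbind, lapply(names(km), function(g)
      data.frame(group = rep(g, nrow(km[[g]])), as.data.frame(km[[g]]),
                 stringsAsFactors = FALSE)))
    write_tsv(kmdf, path("km_curves.tsv"))
    outputs <- c(outputs, "evaluation.tsv", "km_curves.tsv")
    summary$panel_auc <- est$auc
    summary$psa_auc <- dl$auc_b
    summary$delong_p_vs_psa <- dl$p_value
    summary$lrt_p <- lrt$p_value
  }

  digests <- as.list(tools::md5sum(vapply(outputs, path, character(1))))
  names(digests) <- outputs
  # staged runs under one configuration accumulate into one manifest
  if (file.exists(path("manifest.json"))) {
    prior <- tryCatch(jsonlite::read_json(path("manifest.json"),
                                          simplifyVector = FALSE),
                      error = function(e) NULL)
    if (!is.null(prior) &&
        identical(jsonlite::toJSON(prior$config, auto_unbox = TRUE,
                                   digits = NA),
                  jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                   digits = NA))) {
      digests <- utils::modifyList(prior$outputs, digests)
      summary <- utils::modifyList(prior$summary, summary)
      stages <- pipeline_stages[pipeline_stages %in%
                                  union(unlist(prior$stages), stages)]
    }
  }
  manifest <- list(package_version = as.character(
    utils::packageVersion("prmstrat")),
    config = unclass(config), stages = stages,
    outputs = digests, summary = summary)
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a human-readable run report from a manifest
#'
#' The report is generated purely from the manifest (no recomputation),
#' so regenerating it from the same manifest is byte-identical.
#'
#' @param manifest a run manifest from [run_pipeline()], or the path to a
#'   `manifest.json`.
#' @param path optional file to write the report to.
#' @return the report lines, invisibly if written to a file.
#' @export
write_report <- function(manifest, path = NULL) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  s <- manifest$summary
  fmt <- function(x, d = 3) formatC(as.numeric(x), digits = d,
                                    format = "f")
  lines <- c(
    "prmstrat run report",
    "===================",
    paste0("stages: ", paste(unlist(manifest$stages), collapse = " -> ")),
    paste0("seed: ", manifest$config$seed))
  if (!is.null(s$n_patients))
    lines <- c(lines, sprintf("cohort: %d patients, %d recurrence events",
                              s$n_patients, s$n_events))
  if (!is.null(s$n_proteins_kept))
    lines <- c(lines, sprintf(
      "preprocessing: %d proteins kept, %d outlier measurements removed",
      s$n_proteins_kept, s$n_outliers_flagged))
  if (!is.null(s$n_models))
    lines <- c(lines, sprintf(
      "search: %d models; best %s (median AUC %s); equivalence set size %d",
      s$n_models, s$best_model, fmt(s$best_median_auc),
      s$equivalence_set_size),
      paste0("top prevalence features: ",
             paste(unlist(s$top_features), collapse = ", ")))
  if (!is.null(s$final_markers))
    lines <- c(lines, sprintf(
      "final model: markers %s; cutoff %s; %d low / %d high risk",
      paste(unlist(s$final_markers), collapse = "+"), fmt(s$cutoff),
      s$n_low, s$n_high))
  if (!is.null(s$panel_auc))
    lines <- c(lines, sprintf(
      "evaluation: panel AUC %s vs PSA AUC %s (DeLong p %s); KM LRT p %s",
      fmt(s$panel_auc), fmt(s$psa_auc), fmt(s$delong_p_vs_psa, 4),
      fmt(s$lrt_p, 4)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
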