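#' Select a score cutoff maximizing Youden's J
#'
#' Scans the observed scores as candidate thresholds under the decision
#' rule `score > threshold => high risk` and returns the lowest threshold
#' maximizing J = sensitivity + specificity - 1. Because J depends only on
#' the ranking of scores, the selected stratification is invariant to any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric predicted scores.
#' @param labels binary outcome.
#' @return the selected threshold.
#' @export
select_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) stopf("cutoff needs both outcome classes")
  cand <- sort(unique(scores))
  m <- sum(labels); n <- sum(!labels)
  j <- vapply(cand, function(t) {
    sens <- sum(scores > t & labels) / m
    spec <- sum(scores <= t & !labels) / n
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)] # which.max takes the first (lowest) maximizer
}

#' Fit the final risk-stratification model
#'
#' Trains the recurrence random forest on the selected marker panel plus
#' clinical base features over the whole cohort, and derives the score
#' cutoff from the training scores with [select_cutoff()].
#'
#' @param table `quant_table` (or matrix) of protein quantities.
#' @param patients patient table with clinical covariates and
#'   `recurrence_event`.
#' @param markers panel protein ids.
#' @param base clinical base features (`"psa"`, `"gleason"`).
#' @param n_trees trees (default 200).
#' @param seed integer seed.
#' @return a `risk_model` with the fitted forest, `cutoff`, and the
#'   training scores.
#' @export
fit_final <- function(table, patients, markers, base = c("psa", "gleason"),
                      n_trees = 200L, seed = 1L) {
  model <- model_spec(markers, base)
  X <- build_feature_matrix(model, table, patients)
  y <- factor(as.integer(patients$recurrence_event), levels = c(0L, 1L))
  if (length(unique(y)) < 2L) stopf("single outcome class; cannot fit")
  forest <- with_seed(derive_seed(seed, c("final-fit", model$label)),
                      randomForest::randomForest(x = X, y = y,
                                                 ntree = n_trees))
  scores <- stats::predict(forest, X, type = "prob")[, "1"]
  structure(list(spec = model, forest = forest,
                 cutoff = select_cutoff(scores,
                                        patients$recurrence_event),
                 training_scores = stats::setNames(scores,
                                                   patients$sample_id),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("risk_model: %s (%d trees), cutoff %.3f\n",
              x$spec$label, x$n_trees, x$cutoff))
  invisible(x)
}

#' Predict recurrence scores for a cohort
#'
#' @param model a `risk_model`.
#' @param table quantity table for the cohort to score.
#' @param patients patient table (clinical base features, `sample_id`).
#' @return named numeric vector of recurrence-class probabilities in
#'   \[0, 1\].
#' @export
predict_score <- function(model, table, patients) {
  stopifnot(inherits(model, "risk_model"))
  X <- build_feature_matrix(model$spec, table, patients)
  stats::setNames(stats::predict(model$forest, X, type = "prob")[, "1"],
                  patients$sample_id)
}

#' Stratify a cohort into low- and high-risk groups
#'
#' Applies the model's training-derived cutoff with the strict rule
#' `score > cutoff => high risk`, yielding a partition of the cohort.
#'
#' @param model a `risk_model`.
#' @param table,patients cohort to stratify.
#' @return list with `risk_group` (factor low/high per patient),
#'   `scores`, `n_low`, `n_high`, `cutoff`.
#' @export
stratify <- function(model, table, patients) {
  scores <- predict_score(model, table, patients)
  high <- scores > model$cutoff
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  list(risk_group = stats::setNames(grp, patients$sample_id),
       scores = scores, n_low = sum(!high), n_high = sum(high),
       cutoff = model$cutoff)
}
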