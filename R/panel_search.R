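#' Enumerate all candidate marker panels
#'
#' Builds every subset of 1 to `k_max` candidate proteins, each combined
#' with the fixed clinical base features (PSA, optionally biopsy Gleason),
#' in deterministic order: by panel size, then lexicographically.
#'
#' @param candidate_ids character vector of candidate protein ids.
#' @param k_max maximum panel size (clamped to the number of candidates).
#' @param base_features clinical features attached to every panel; must be
#'   disjoint from the candidates.
#' @return list of `model_spec` objects (fields `markers`, `base`,
#'   `label`).
#' @export
enumerate_models <- function(candidate_ids, k_max = 5L,
                             base_features = "psa") {
  stopifnot(length(candidate_ids) >= 1L, k_max >= 1L)
  if (anyDuplicated(candidate_ids)) stopf("duplicate candidate ids")
  if (length(intersect(candidate_ids, base_features)))
    stopf("candidates overlap base features")
  k_max <- min(as.integer(k_max), length(candidate_ids))
  ids <- sort(candidate_ids)
  out <- vector("list", sum(choose(length(ids), seq_len(k_max))))
  pos <- 0L
  for (k in seq_len(k_max)) {
    comb <- utils::combn(ids, k, simplify = FALSE)
    for (cc in comb) {
      pos <- pos + 1L
      out[[pos]] <- model_spec(cc, base_features)
    }
  }
  out
}

#' Construct a model specification
#' @param markers candidate protein ids in the panel.
#' @param base clinical base features (always carried along).
#' @return a `model_spec`.
#' @export
model_spec <- function(markers, base = "psa") {
  structure(list(markers = as.character(markers),
                 base = as.character(base),
                 label = paste(c(sort(as.character(markers)),
                                 as.character(base)), collapse = "+")),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$label, "\n")
  invisible(x)
}

#' Draw a paired bootstrap cross-validation plan
#'
#' `n_folds` resamples of size `n_samples` drawn with replacement; each
#' fold's test set is its out-of-bag complement. A fold whose out-of-bag
#' set lacks either outcome class is redrawn (bounded retries). The same
#' plan object is applied to every candidate model, which is what makes
#' the per-fold AUCs of different models paired.
#'
#' @param n_samples cohort size.
#' @param labels binary outcome per sample (both classes required).
#' @param n_folds number of bootstrap folds (default 50).
#' @param seed integer seed.
#' @param max_retries redraw bound per fold.
#' @return a `bootstrap_plan` with `train` / `test` index lists, `seed`,
#'   and a `hash` identifying the plan.
#' @export
make_bootstrap_plan <- function(n_samples, labels, n_folds = 50L,
                                seed = 1L, max_retries = 100L) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == n_samples)
  if (length(unique(labels)) < 2L)
    stopf("bootstrap plan needs both outcome classes")
  with_seed(derive_seed(seed, "bootstrap-plan"), {
    train <- vector("list", n_folds)
    test <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      for (try in seq_len(max_retries)) {
        idx <- sample.int(n_samples, n_samples, replace = TRUE)
        oob <- setdiff(seq_len(n_samples), idx)
        if (length(oob) && length(unique(labels[oob])) == 2L) break
        if (try == max_retries)
          stopf("could not draw a fold with both classes out-of-bag after %d tries",
                max_retries)
      }
      train[[f]] <- idx
      test[[f]] <- oob
    }
    structure(list(train = train, test = test, n_samples = n_samples,
                   n_folds = as.integer(n_folds), seed = as.integer(seed),
                   hash = label_hash(vapply(train, function(i)
                     paste(i, collapse = ","), character(1)))),
              class = "bootstrap_plan")
  })
}

# Assemble the feature matrix for a model: marker columns from the quantity
# table, clinical base features from the patient table, aligned by sample.
build_feature_matrix <- function(model, table, patients) {
  stopifnot(inherits(model, "model_spec"))
  mat <- if (inherits(table, "quant_table")) table$mat else as.matrix(table)
  miss <- setdiff(model$markers, colnames(mat))
  if (length(miss))
    stopf("model feature(s) absent from quantity table: %s",
          paste(miss, collapse = ", "))
  idx <- match(patients$sample_id, rownames(mat))
  if (anyNA(idx)) stopf("patient sample(s) absent from quantity table")
  X <- mat[idx, model$markers, drop = FALSE]
  base_cols <- list(psa = patients$psa_ng_ml, gleason = patients$gleason_bx)
  for (b in model$base) {
    if (!b %in% names(base_cols))
      stopf("unknown base feature '%s' (use 'psa' and/or 'gleason')", b)
    X <- cbind(X, base_cols[[b]])
    colnames(X)[ncol(X)] <- b
  }
  if (anyNA(X)) stopf("feature matrix contains missing values; impute first")
  X
}

#' Evaluate one model by paired bootstrapped cross-validation
#'
#' For every fold of the plan, fits a random-forest classifier (recurrence
#' vs no recurrence) on the bootstrap training resample, scores the
#' out-of-bag samples with the recurrence class probability, and computes
#' the fold AUC. Forests are seeded from (plan seed, fold, model label) so
#' results are reproducible and independent of evaluation order.
#'
#' @param model a `model_spec`.
#' @param table `quant_table` (or samples-by-proteins matrix).
#' @param patients patient table with `sample_id`, `psa_ng_ml`,
#'   `gleason_bx`, `recurrence_event`.
#' @param plan a `bootstrap_plan`.
#' @param n_trees trees per forest (default 200).
#' @return a `cv_result` with `fold_aucs`, `median_auc`, `mean_auc`,
#'   `sd_auc`, `plan_hash`.
#' @export
evaluate_model <- function(model, table, patients, plan, n_trees = 200L) {
  stopifnot(inherits(plan, "bootstrap_plan"),
            nrow(patients) == plan$n_samples)
  X <- build_feature_matrix(model, table, patients)
  y <- factor(as.integer(patients$recurrence_event), levels = c(0L, 1L))
  mhash <- label_hash(model$label)
  fold_aucs <- vapply(seq_len(plan$n_folds), function(f) {
    tr <- plan$train[[f]]
    te <- plan$test[[f]]
    with_seed(derive_seed(plan$seed, c("fold", f, mhash)), {
      rf <- randomForest::randomForest(x = X[tr, , drop = FALSE],
                                       y = y[tr], ntree = n_trees)
      score <- stats::predict(rf, X[te, , drop = FALSE],
                              type = "prob")[, "1"]
      auc(score, patients$recurrence_event[te])
    })
  }, numeric(1))
  structure(list(model = model, fold_aucs = fold_aucs,
                 median_auc = stats::median(fold_aucs),
                 mean_auc = mean(fold_aucs),
                 sd_auc = stats::sd(fold_aucs),
                 n_trees = as.integer(n_trees),
                 plan_hash = plan$hash),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result %s: median AUC %.3f (mean %.3f, sd %.3f, %d folds)\n",
              x$model$label, x$median_auc, x$mean_auc, x$sd_auc,
              length(x$fold_aucs)))
  invisible(x)
}

#' Evaluate every enumerated model under one paired plan
#'
#' @param models list of `model_spec` from [enumerate_models()].
#' @param table,patients,plan,n_trees as in [evaluate_model()].
#' @param progress_every log a progress line every this many models
#'   (0 = silent).
#' @return list of `cv_result`, in the enumeration order.
#' @export
search_panels <- function(models, table, patients, plan, n_trees = 200L,
                          progress_every = 0L) {
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    out[[i]] <- evaluate_model(models[[i]], table, patients, plan, n_trees)
    if (progress_every > 0L && i %% progress_every == 0L)
      message(sprintf("evaluated %d / %d models", i, length(models)))
  }
  out
}

#' Rank models and build the statistical equivalence set
#'
#' Models are ranked by median fold AUC (ties broken by mean AUC, then by
#' label for determinism). The best model's fold AUCs are compared with
#' every other model's by a two-sided paired t-test; p-values are
#' Bonferroni-adjusted over the number of comparisons, and every model
#' whose adjusted p is at or above `alpha` joins the best model in the
#' equivalence set. An identically-performing model (all paired
#' differences zero) is not significantly different by convention.
#'
#' @param results list of `cv_result` sharing one bootstrap plan.
#' @param alpha significance level (default 0.05).
#' @return an `equivalence_set`: `ranked` (all results, ranked),
#'   `members`, `adjusted_p` (per ranked model; NA for the best),
#'   `alpha`.
#' @export
rank_and_equivalence <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1L)
  nf <- vapply(results, function(r) length(r$fold_aucs), integer(1))
  if (length(unique(nf)) != 1L) stopf("fold counts differ across results")
  if (length(unique(vapply(results, function(r)
    as.numeric(r$plan_hash), numeric(1)))) != 1L)
    stopf("results were not evaluated under one shared bootstrap plan")
  ord <- order(-vapply(results, `[[`, numeric(1), "median_auc"),
               -vapply(results, `[[`, numeric(1), "mean_auc"),
               vapply(results, function(r) r$model$label, character(1)))
  ranked <- results[ord]
  best <- ranked[[1]]
  m <- length(ranked) - 1L
  adj_p <- rep(NA_real_, length(ranked))
  if (m > 0L) {
    for (i in seq_len(m) + 1L) {
      d <- best$fold_aucs - ranked[[i]]$fold_aucs
      p <- if (stats::sd(d) < .Machine$double.eps^0.5) {
        # degenerate paired t: identical folds are equivalent by
        # convention; a constant non-zero shift is unambiguously different
        if (abs(mean(d)) < .Machine$double.eps^0.5) 1 else 0
      } else {
        stats::t.test(best$fold_aucs, ranked[[i]]$fold_aucs,
                      paired = TRUE)$p.value
      }
      adj_p[i] <- min(1, p * m)
    }
  }
  member_idx <- c(1L, which(adj_p >= alpha))
  structure(list(ranked = ranked, members = ranked[member_idx],
                 member_idx = member_idx, adjusted_p = adj_p,
                 alpha = alpha),
            class = "equivalence_set")
}

#' @export
print.equivalence_set <- function(x, ...) {
  cat(sprintf(
    "equivalence_set: %d of %d models indistinguishable from the best (%s, median AUC %.3f) at alpha %.2f\n",
    length(x$members), length(x$ranked), x$ranked[[1]]$model$label,
    x$ranked[[1]]$median_auc, x$alpha))
  invisible(x)
}

#' Feature prevalence across the equivalence set
#'
#' Fraction of equivalence-set member models containing each candidate
#' marker (base features excluded), sorted descending with lexicographic
#' tie-break — the stability measure used to pick the final panel.
#'
#' @param eq an `equivalence_set`.
#' @return data.frame with `feature` and `prevalence`.
#' @export
feature_prevalence <- function(eq) {
  stopifnot(inherits(eq, "equivalence_set"), length(eq$members) >= 1L)
  feats <- unlist(lapply(eq$members, function(r) unique(r$model$markers)))
  tab <- table(feats) / length(eq$members)
  df <- data.frame(feature = names(tab), prevalence = as.numeric(tab),
                   stringsAsFactors = FALSE)
  df[order(-df$prevalence, df$feature), , drop = FALSE]
}
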