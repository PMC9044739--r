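test_that("model enumeration counts and order are deterministic", {
  expect_length(enumerate_models(sprintf("P%02d", 1:3), 2), 6)
  expect_length(enumerate_models(sprintf("P%02d", 1:5), 5), 2^5 - 1)
  # k_max beyond the candidate count clamps
  expect_length(enumerate_models(c("A", "B"), 10), 3)
  mods <- enumerate_models(c("B", "A", "C"), 2)
  labs <- vapply(mods, function(m) m$label, character(1))
  expect_equal(labs[1:3], c("A+psa", "B+psa", "C+psa"))
  expect_true(all(vapply(mods, function(m) "psa" %in% m$base, logical(1))))
  expect_error(enumerate_models(c("A", "psa"), 1), "overlap")
})

test_that("bootstrap plans are paired, seeded, and class-guarded", {
  labels <- rep(c(TRUE, FALSE), 50)
  p1 <- make_bootstrap_plan(100, labels, 25, seed = 3)
  p2 <- make_bootstrap_plan(100, labels, 25, seed = 3)
  expect_identical(p1$train, p2$train)
  expect_identical(p1$hash, p2$hash)
  # out-of-bag sets are the complements and contain both classes
  for (f in 1:25) {
    expect_setequal(union(unique(p1$train[[f]]), p1$test[[f]]), 1:100)
    expect_length(unique(labels[p1$test[[f]]]), 2)
  }
  # expected out-of-bag fraction ~ (1 - 1/n)^n ~ 0.366
  oob_frac <- mean(vapply(p1$test, length, numeric(1))) / 100
  expect_lt(abs(oob_frac - (1 - 1 / 100)^100), 0.03)
  expect_error(make_bootstrap_plan(10, rep(TRUE, 10), 5, 1), "both")
})

test_that("a perfectly separating feature yields median AUC 1", {
  nc <- null_cohort(77, n = 60)
  mat <- cbind(nc$table,
               LEAK = 2^(15 + 2 * nc$patients$recurrence_event))
  plan <- make_bootstrap_plan(60, nc$patients$recurrence_event, 8,
                              seed = 5)
  res <- evaluate_model(model_spec("LEAK", "psa"), mat, nc$patients,
                        plan, n_trees = 100)
  expect_equal(res$median_auc, 1)
})

test_that("fold AUCs equal the pair-counting oracle and results are paired", {
  sim <- tiny_quantified(seed = 41, n_patients = 40, mnar_prob = 0,
                         mcar_prob = 0)
  plan <- make_bootstrap_plan(40, sim$patients$recurrence_event, 6,
                              seed = 6)
  model <- model_spec(candidate_proteins(sim$table)[1], "psa")
  res <- evaluate_model(model, sim$table, sim$patients, plan,
                        n_trees = 50)
  expect_equal(res$median_auc, median(res$fold_aucs))
  expect_true(all(res$fold_aucs >= 0 & res$fold_aucs <= 1))
  expect_identical(res$plan_hash, plan$hash)
  # recompute one fold by hand against the brute-force oracle
  X <- prmstrat:::build_feature_matrix(model, sim$table, sim$patients)
  y <- factor(as.integer(sim$patients$recurrence_event),
              levels = c(0L, 1L))
  mh <- prmstrat:::label_hash(model$label)
  for (f in c(1, 4)) {
    tr <- plan$train[[f]]; te <- plan$test[[f]]
    score <- prmstrat:::with_seed(
      prmstrat:::derive_seed(plan$seed, c("fold", f, mh)), {
        rf <- randomForest::randomForest(x = X[tr, , drop = FALSE],
                                         y = y[tr], ntree = 50)
        predict(rf, X[te, , drop = FALSE], type = "prob")[, "1"]
      })
    expect_equal(res$fold_aucs[f],
                 auc_pair_oracle(score,
                                 sim$patients$recurrence_event[te]))
  }
})

test_that("evaluation errors on absent features", {
  sim <- tiny_quantified(seed = 42, n_patients = 30)
  plan <- make_bootstrap_plan(30, sim$patients$recurrence_event, 3,
                              seed = 1)
  expect_error(evaluate_model(model_spec("GHOST", "psa"), sim$table,
                              sim$patients, plan),
               "GHOST")
})

test_that("equivalence set follows the paired-t / Bonferroni rules", {
  mk <- function(aucs, label) structure(
    list(model = model_spec(label, "psa"), fold_aucs = aucs,
         median_auc = median(aucs), mean_auc = mean(aucs),
         sd_auc = sd(aucs), plan_hash = 99), class = "cv_result")
  set.seed(8)
  base <- 0.75 + rnorm(20, 0, 0.04)
  resA <- mk(base, "A")
  resB <- mk(base, "B")              # identical folds: member by convention
  resC <- mk(base - 0.3, "C")        # constant large shift: excluded
  resD <- mk(base - rnorm(20, 0.002, 0.02), "D") # tiny shift: member
  eq <- rank_and_equivalence(list(resC, resB, resA, resD), alpha = 0.05)
  labs <- vapply(eq$members, function(r) r$model$markers, character(1))
  expect_true(all(c("A", "B", "D") %in% labs))
  expect_false("C" %in% labs)
  # Bonferroni adjustment is min(1, p * m) over m = 3 comparisons
  d <- eq$ranked[[1]]$fold_aucs - resD$fold_aucs
  p_raw <- t.test(eq$ranked[[1]]$fold_aucs, resD$fold_aucs,
                  paired = TRUE)$p.value
  i <- which(vapply(eq$ranked, function(r) r$model$markers,
                    character(1)) == "D")
  expect_equal(eq$adjusted_p[i], min(1, p_raw * 3))
  # mixed plans are rejected
  resE <- mk(base, "E"); resE$plan_hash <- 1
  expect_error(rank_and_equivalence(list(resA, resE)), "shared")
})

test_that("feature prevalence counts member fractions with stable order", {
  mk <- function(markers) structure(
    list(model = model_spec(markers, "psa"),
         fold_aucs = rep(0.7, 5), median_auc = 0.7, mean_auc = 0.7,
         sd_auc = 0, plan_hash = 1), class = "cv_result")
  eq <- structure(list(members = list(mk(c("FN1", "VTN")))),
                  class = "equivalence_set")
  pv <- feature_prevalence(eq)
  expect_equal(pv$prevalence, c(1, 1))
  expect_equal(pv$feature, c("FN1", "VTN")) # tie broken lexicographically

  eq2 <- structure(list(members = list(mk(c("A", "B")), mk(c("A", "C")))),
                   class = "equivalence_set")
  pv2 <- feature_prevalence(eq2)
  expect_equal(pv2$feature, c("A", "B", "C"))
  expect_equal(pv2$prevalence, c(1, 0.5, 0.5))
})

test_that("adding a separating feature does not lower the median AUC", {
  nc <- null_cohort(88, n = 60)
  mat <- cbind(nc$table,
               LEAK = 2^(15 + 2 * nc$patients$recurrence_event))
  plan <- make_bootstrap_plan(60, nc$patients$recurrence_event, 8,
                              seed = 9)
  weak <- evaluate_model(model_spec("NOISE01", "psa"), mat, nc$patients,
                         plan, n_trees = 100)
  strong <- evaluate_model(model_spec(c("NOISE01", "LEAK"), "psa"), mat,
                           nc$patients, plan, n_trees = 100)
  expect_gte(strong$median_auc, weak$median_auc - 0.05)
})
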