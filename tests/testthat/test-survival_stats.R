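test_that("AUC handles separation, ties, and matches the pair oracle", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both")
  set.seed(61)
  for (rep in 1:15) {
    n <- sample(8:25, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # induce ties
    labels <- rbinom(n, 1, 0.5) == 1
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), auc_pair_oracle(scores, labels))
    # complement identity (tie-free scores)
    sc2 <- rnorm(n)
    expect_equal(auc(sc2, labels) + auc(-sc2, labels), 1)
  }
})

test_that("DeLong estimate and test agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(62)
  n <- 120
  labels <- rbinom(n, 1, 0.45) == 1
  x <- rnorm(n) + labels
  a <- x + rnorm(n, 0, 0.8)
  b <- 0.4 * x + rnorm(n, 0, 1)
  est <- auc_estimate(a, labels)
  r <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  expect_equal(est$auc, as.numeric(pROC::auc(r)))
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  expect_equal(c(est$ci_low, est$ci_high), ci[c(1, 3)], tolerance = 1e-6)

  dt <- delong_test(a, b, labels)
  rt <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<"),
                       pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dt$p_value, rt$p.value, tolerance = 1e-9)
})

test_that("DeLong test degeneracy, symmetry, and bootstrap variance", {
  set.seed(63)
  labels <- rbinom(80, 1, 0.5) == 1
  labels[1:2] <- c(TRUE, FALSE)
  a <- rnorm(80) + labels
  expect_warning(self <- delong_test(a, a, labels), "degenerate")
  expect_equal(self$difference, 0)
  expect_equal(self$p_value, 1)

  b <- rnorm(80) + 0.5 * labels
  ab <- delong_test(a, b, labels)
  ba <- delong_test(b, a, labels)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$difference, -ba$difference)

  # variance matches a paired-bootstrap variance of the AUC difference
  B <- 2000
  diffs <- vapply(1:B, function(i) {
    idx <- sample(80, replace = TRUE)
    if (length(unique(labels[idx])) < 2) return(NA_real_)
    auc(a[idx], labels[idx]) - auc(b[idx], labels[idx])
  }, numeric(1))
  boot_var <- var(diffs, na.rm = TRUE)
  expect_lt(abs(ab$variance - boot_var) / boot_var, 0.35)
})

test_that("Kaplan-Meier matches the hand product-limit calculation", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, FALSE))$all
  expect_equal(km$time, c(1, 2))
  expect_equal(km$n_risk, c(3, 2))
  expect_equal(km$survival, c(2 / 3, 1 / 3))
  # no events: a flat curve at 1 (no steps at all)
  flat <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))$all
  expect_equal(nrow(flat), 0)
  # all events, distinct times, no censoring: S(t_k) = (n - k) / n
  n <- 7
  full <- km_estimate(seq_len(n), rep(TRUE, n))$all
  expect_equal(full$survival, (n - seq_len(n)) / n)
})

test_that("Kaplan-Meier agrees with the survival package on mixed data", {
  skip_if_not_installed("survival")
  set.seed(64)
  n <- 150
  times <- round(rexp(n, 0.1), 1) # ties likely after rounding
  events <- rbinom(n, 1, 0.6) == 1
  group <- sample(c("g1", "g2"), n, replace = TRUE)
  km <- km_estimate(times, events, group)
  sf <- survival::survfit(survival::Surv(times, events) ~ group)
  # compare per group at event times
  for (g in c("g1", "g2")) {
    s <- summary(sf[paste0("group=", g) == names(sf$strata)],
                 times = km[[g]]$time)
    expect_equal(km[[g]]$survival, s$surv, tolerance = 1e-12)
  }
})

test_that("Cox LRT beta matches grid search and coxph on a small cohort", {
  times <- c(2, 4, 5, 7, 8, 9, 12, 14, 20, 25)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
              FALSE)
  group <- rep(c("hi", "lo"), 5)
  fit <- lrt_two_groups(times, events, group)
  # coarse-to-fine grid maximizer of the Breslow partial likelihood
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, prmstrat:::cox_binary_loglik, numeric(1),
               times = times, events = events,
               x = as.numeric(group == sort(unique(group))[2]))
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-4 + 1e-8)

  skip_if_not_installed("survival")
  cf <- survival::coxph(survival::Surv(times, events) ~ group,
                        ties = "breslow")
  expect_equal(unname(fit$beta), unname(stats::coef(cf)),
               tolerance = 1e-5)
  expect_equal(fit$statistic,
               2 * diff(cf$loglik), tolerance = 1e-6)
})

test_that("LRT symmetry, error handling, and boundary behaviour", {
  times <- c(1, 3, 4, 6, 8, 10)
  events <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  grp <- c("a", "b", "a", "b", "a", "b")
  f1 <- lrt_two_groups(times, events, grp)
  # relabeling the groups flips the sign of beta, statistic unchanged
  swapped <- lrt_two_groups(times, events, ifelse(grp == "a", "b", "a"))
  expect_equal(swapped$beta, -f1$beta, tolerance = 1e-6)
  expect_equal(swapped$statistic, f1$statistic, tolerance = 1e-8)
  expect_error(lrt_two_groups(times, rep(FALSE, 6), grp), "no events")
  expect_error(lrt_two_groups(times, events, rep("a", 6)), "two groups")
  # complete separation warns
  expect_warning(
    lrt_two_groups(c(1, 2, 3, 10, 11, 12),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                   c("x", "x", "x", "y", "y", "y")),
    "boundary")
})
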