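#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outranks a random negative,
#' ties counted one half — computed from ranks, so it is exact and
#' invariant to any strictly monotone transform of the scores.
#'
#' @param scores numeric score per subject (higher = more positive).
#' @param labels binary outcome (logical, or coercible 0/1).
#' @return the AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  m <- sum(labels)
  n <- sum(!labels)
  if (m == 0L || n == 0L) stopf("AUC needs both outcome classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties half); and the mirror for negatives.
placements <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), # v01 on the "negative
       auc = mean(cmp))                              # beats positive" scale
}

#' AUC with a DeLong confidence interval
#'
#' @inheritParams auc
#' @param conf_level confidence level.
#' @return list with `auc`, `ci_low`, `ci_high`, `se`, `method`.
#' @export
auc_estimate <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  pl <- placements(scores, labels)
  m <- sum(labels); n <- sum(!labels)
  v01_pos <- 1 - pl$v01 # back to the P(positive beats negative) scale
  se <- sqrt(stats::var(pl$v10) / m + stats::var(v01_pos) / n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- pl$auc
  list(auc = est,
       ci_low = max(0, est - z * se), ci_high = min(1, est + z * se),
       se = se, method = "delong")
}

#' DeLong test for two correlated ROC curves
#'
#' Paired comparison of the AUCs of two scores measured on the same
#' subjects, using the covariance of their placement values; the p-value
#' comes from the normal reference distribution. A degenerate comparison
#' (zero variance of the difference, e.g. identical scores) returns
#' p = 1 with a warning.
#'
#' @param scores_a,scores_b two score vectors for the same subjects.
#' @param labels binary outcome.
#' @return list with `auc_a`, `auc_b`, `difference`, `variance`, `z`,
#'   `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  if (m < 2L || n < 2L) stopf("DeLong test needs >= 2 subjects per class")
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(1 - pa$v01, 1 - pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    if (abs(d) > .Machine$double.eps^0.5)
      warning("zero DeLong variance with a non-zero AUC difference")
    else warning("degenerate DeLong comparison (zero variance); p = 1")
    return(list(auc_a = pa$auc, auc_b = pb$auc, difference = d,
                variance = v, z = 0, p_value = 1))
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, difference = d, variance = v,
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Kaplan-Meier (product-limit) survival estimate per group
#'
#' @param times follow-up times (>= 0).
#' @param events event indicator (TRUE = event, FALSE = censored).
#' @param group group label per subject (optional; one curve if omitted).
#' @return named list of `survival_curve` data.frames with columns `time`
#'   (distinct event times), `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(times, events, group = NULL) {
  stopifnot(all(times >= 0), length(times) == length(events))
  events <- as.logical(events)
  if (is.null(group)) group <- rep("all", length(times))
  stopifnot(length(group) == length(times))
  out <- lapply(split(seq_along(times), group), function(idx) {
    if (!length(idx)) stopf("empty group")
    tt <- times[idx]; ee <- events[idx]
    et <- sort(unique(tt[ee]))
    n_risk <- vapply(et, function(t) sum(tt >= t), numeric(1))
    n_event <- vapply(et, function(t) sum(tt == t & ee), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    structure(data.frame(time = et, n_risk = n_risk, n_event = n_event,
                         survival = surv),
              class = c("survival_curve", "data.frame"))
  })
  if (any(vapply(split(seq_along(times), group), length, 1L) == 0L))
    stopf("empty group")
  out
}

# Breslow partial log-likelihood for a single binary covariate: the risk
# set sum collapses to n0(t) + n1(t) * exp(beta).
cox_binary_loglik <- function(beta, times, events, x) {
  et <- sort(unique(times[events]))
  ll <- 0
  for (t in et) {
    at_risk <- times >= t
    d_idx <- times == t & events
    d <- sum(d_idx)
    n1 <- sum(x[at_risk])
    n0 <- sum(at_risk) - n1
    ll <- ll + beta * sum(x[d_idx]) - d * log(n0 + n1 * exp(beta))
  }
  ll
}

#' Likelihood-ratio test for survival separation of two groups
#'
#' Fits a proportional-hazards model with the single binary group
#' covariate by maximizing the Breslow partial likelihood, and reports
#' the likelihood-ratio statistic 2(l(beta_hat) - l(0)) against the
#' chi-square distribution with one degree of freedom. Complete or
#' near-complete separation (the estimate running to the boundary) is
#' reported with a warning.
#'
#' @param times follow-up times.
#' @param events event indicator.
#' @param group two-level group label (the higher-sorting level is coded 1).
#' @return list with `beta`, `statistic`, `p_value`, `levels`.
#' @export
lrt_two_groups <- function(times, events, group) {
  events <- as.logical(events)
  stopifnot(length(times) == length(events), length(group) == length(times))
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2L) stopf("need exactly two groups, got %d", length(lev))
  if (!any(events)) stopf("no events; likelihood-ratio test undefined")
  x <- as.numeric(as.character(group) == lev[2])
  bound <- 25
  opt <- stats::optimize(cox_binary_loglik, c(-bound, bound), maximum = TRUE,
                         times = times, events = events, x = x,
                         tol = 1e-10)
  beta <- opt$maximum
  if (abs(beta) > bound - 1) {
    warning("group effect at the likelihood boundary (complete separation)")
    beta <- sign(beta) * (bound - 1)
  }
  stat <- 2 * (cox_binary_loglik(beta, times, events, x) -
                 cox_binary_loglik(0, times, events, x))
  stat <- max(stat, 0)
  list(beta = beta, statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       levels = lev)
}
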