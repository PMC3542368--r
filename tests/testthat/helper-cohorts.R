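# Shared fixture builders. Everything is generated in code at test time.

# Small random censored cohort for oracle comparisons.
random_cohort <- function(n, event_prob = 0.7, rate = 0.05) {
  time <- rexp(n, rate)
  event <- rbinom(n, 1L, event_prob)
  if (sum(event) < 2) event[sample.int(n, 2)] <- 1L
  surv_outcome(time, event)
}

# Binary covariate guaranteed non-constant.
random_group <- function(n, p = 0.5) {
  g <- rbinom(n, 1L, p)
  if (all(g == 0L)) g[1L] <- 1L
  if (all(g == 1L)) g[1L] <- 0L
  g
}

# Direct threshold-sweep ROC of a binary outcome (the uncensored-limit
# oracle): positive calls are score > c for each unique score c.
empirical_binary_roc <- function(scores, case) {
  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(c) mean(scores[case == 1L] > c), numeric(1))
  fpr <- vapply(thr, function(c) mean(scores[case == 0L] > c), numeric(1))
  fpr_c <- c(1, fpr, 0)
  tpr_c <- c(1, tpr, 0)
  ord <- order(fpr_c, tpr_c)
  auc <- sum(diff(fpr_c[ord]) *
               (head(tpr_c[ord], -1) + tail(tpr_c[ord], -1)) / 2)
  list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc)
}

# Hand accumulation of the two-group log-rank O, E, V over event times
# (independent of the package's compiled path).
hand_logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  oe <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(statistic = oe^2 / v, oe = oe, v = v)
}

# Grid-search maximizer of the Cox partial likelihood (Breslow) for tiny
# instances; the independent oracle for the analytic Newton solver.
grid_cox_loglik <- function(beta, x, time, event) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}
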