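#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator of the survivor function with Greenwood variance,
#' the median survival time, and a 95% confidence interval for the median
#' obtained by inverting the log(-log)-transformed pointwise confidence band
#' (the convention of Stata's `sts` and of `survfit(conf.type = "log-log")`).
#'
#' Censored observations tied with events at the same time are considered at
#' risk at that time (censored-after-event convention).
#'
#' @param outcome A [surv_outcome].
#' @param conf_level Confidence level for the band used to invert the median
#'   interval (default 0.95).
#'
#' @return An object of class `km_curve`: list with `event_times` (distinct
#'   times with at least one event, ascending), `n_risk`, `n_event`,
#'   `survival`, `greenwood_var`, `median` (NA if the curve never reaches
#'   0.5), and `median_ci` (bounds may be NA).
#' @examples
#' km_estimate(surv_outcome(c(1, 2, 3), c(1, 1, 1)))
#' @export
km_estimate <- function(outcome, conf_level = 0.95) {
  outcome <- as_surv_outcome(outcome)
  ord <- order(outcome$time)
  time <- outcome$time[ord]
  event <- outcome$event[ord]
  ut <- unique(time[event == 1L])
  n <- length(time)
  if (length(ut) == 0L) {
    out <- structure(list(event_times = numeric(0), n_risk = integer(0),
                          n_event = integer(0), survival = numeric(0),
                          greenwood_var = numeric(0), median = NA_real_,
                          median_ci = c(lower = NA_real_, upper = NA_real_),
                          n = n, conf_level = conf_level),
                     class = "km_curve")
    return(out)
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), integer(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1L), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: Var(S) = S^2 * cumsum(d / (r (r - d)))
  inc <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0)
  gw_sum <- cumsum(inc)
  greenwood_var <- surv^2 * gw_sum

  # crossing tolerance guards against cumprod() landing a hair above 0.5
  tol <- sqrt(.Machine$double.eps)
  med <- if (any(surv <= 0.5 + tol)) ut[which(surv <= 0.5 + tol)[1L]] else NA_real_

  # log(-log) pointwise band (undefined where S is 0 or 1), then first
  # crossings of 0.5
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ok <- surv > tol & surv < 1 - tol
  se_ll <- rep(NA_real_, length(surv))
  se_ll[ok] <- sqrt(gw_sum[ok]) / abs(log(surv[ok]))
  lower <- upper <- rep(NA_real_, length(surv))
  lower[ok] <- surv[ok]^exp(z * se_ll[ok])
  upper[ok] <- surv[ok]^exp(-z * se_ll[ok])
  ci_low <- if (any(lower <= 0.5 + tol, na.rm = TRUE)) ut[which(lower <= 0.5 + tol)[1L]] else NA_real_
  ci_high <- if (any(upper <= 0.5 + tol, na.rm = TRUE)) ut[which(upper <= 0.5 + tol)[1L]] else NA_real_

  structure(list(event_times = ut, n_risk = n_risk, n_event = n_event,
                 survival = surv, greenwood_var = greenwood_var,
                 median = med, median_ci = c(lower = ci_low, upper = ci_high),
                 n = n, conf_level = conf_level),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d distinct event times, median = %s (%.0f%% CI %s-%s)\n",
              x$n, length(x$event_times),
              formatC(x$median, digits = 3, format = "fg"),
              100 * x$conf_level,
              formatC(x$median_ci[1], digits = 3, format = "fg"),
              formatC(x$median_ci[2], digits = 3, format = "fg")))
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$event_times, n_risk = x$n_risk, n_event = x$n_event,
             survival = x$survival, greenwood_var = x$greenwood_var)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) two-group log-rank test: at each distinct event time
#' the observed number of events in group 1 is compared with its
#' hypergeometric expectation; the statistic is `(sum(O - E))^2 / sum(V)` and
#' the p-value is the upper tail of a chi-square with 1 df.
#'
#' @param outcome A [surv_outcome].
#' @param group Binary membership indicator (0/1 or logical) per patient;
#'   group 1 is the "exposed" (e.g. mutated) group.
#'
#' @return Object of class `logrank_result`: `statistic`, `p_value`, and
#'   `observed_minus_expected` (per group, group0 then group1).
#' @examples
#' oc <- surv_outcome(c(1, 2, 3, 4), c(1, 1, 1, 0))
#' logrank_test(oc, c(1, 0, 1, 0))
#' @export
logrank_test <- function(outcome, group) {
  outcome <- as_surv_outcome(outcome)
  group <- as.integer(group)
  if (length(group) != length(outcome)) {
    stop("`group` length must match the outcome", call. = FALSE)
  }
  if (anyNA(group) || !all(group %in% c(0L, 1L))) {
    stop("`group` must be binary 0/1", call. = FALSE)
  }
  if (all(group == 0L) || all(group == 1L)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  sc <- logrank_screen_cpp(matrix(group, ncol = 1), outcome$time, outcome$event)
  v <- sc$variance[1L]
  oe <- sc$obs_minus_exp[1L]
  stat <- if (v > 0) oe^2 / v else 0
  structure(list(statistic = stat,
                 p_value = if (v > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1,
                 observed_minus_expected = c(group0 = -oe, group1 = oe),
                 variance = v),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chisq = %.4g on 1 df, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson from the zero
#' vector, with step-halving when a step would decrease the likelihood.
#' Convergence is declared when the largest score component is at most
#' `1e-9` or the relative log-likelihood change is at most `1e-12`;
#' monotone-likelihood cases are flagged as non-converged after `maxit`
#' iterations rather than raised as errors.
#'
#' @param x Numeric covariate matrix, one row per patient (column names used
#'   in the output when present).
#' @param outcome A [surv_outcome].
#' @param ties Tie handling for the partial likelihood: `"efron"` (default)
#'   or `"breslow"`.
#' @param maxit Maximum Newton iterations.
#'
#' @return Object of class `cox_fit`: `coefficients`, `standard_errors`,
#'   `loglik` (at the optimum), `loglik_null` (at zero), `converged`,
#'   `n_iterations`, `vcov`, `ties`.
#' @examples
#' oc <- surv_outcome(c(1, 2, 3), c(1, 1, 1))
#' cox_fit(cbind(x = c(1, 0, 1)), oc, ties = "breslow")
#' @export
cox_fit <- function(x, outcome, ties = c("efron", "breslow"), maxit = 50L) {
  ties <- match.arg(ties)
  outcome <- as_surv_outcome(outcome)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(outcome)) {
    stop("covariate rows must match the outcome length", call. = FALSE)
  }
  if (ncol(x) < 1L) stop("at least one covariate is required", call. = FALSE)
  if (sum(outcome$event) == 0L) stop("no events in the outcome", call. = FALSE)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    nm <- colnames(x)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop(sprintf("constant covariate(s): %s", paste(nm, collapse = ", ")),
         call. = FALSE)
  }
  fit <- cox_fit_cpp(x, outcome$time, outcome$event, efron = ties == "efron",
                     maxit = as.integer(maxit))
  cf <- as.numeric(fit$coefficients)
  se <- as.numeric(fit$se)
  names(cf) <- names(se) <- colnames(x)
  structure(list(coefficients = cf, standard_errors = se,
                 loglik = fit$loglik, loglik_null = fit$loglik0,
                 converged = fit$converged, n_iterations = fit$n_iterations,
                 vcov = fit$vcov, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d covariate(s), loglik %.4f (null %.4f), %s in %d iteration(s)\n",
              length(x$coefficients), x$loglik, x$loglik_null,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  print(data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                   se = x$standard_errors, check.names = FALSE))
  invisible(x)
}

#' Cox linear predictor (risk score)
#'
#' Dot product of each covariate row with the fitted coefficients; no
#' intercept, no centering beyond what the caller has applied.
#'
#' @param fit A [cox_fit].
#' @param x Covariate matrix whose columns match the fit.
#' @return Numeric risk score per row of `x`.
#' @export
cox_linear_predictor <- function(fit, x) {
  if (!inherits(fit, "cox_fit")) stop("`fit` must be a cox_fit", call. = FALSE)
  x <- as.matrix(x)
  if (ncol(x) != length(fit$coefficients)) {
    stop("covariate columns do not match the fitted coefficients", call. = FALSE)
  }
  as.numeric(x %*% fit$coefficients)
}

#' Hazard ratio between two groups
#'
#' Univariate Cox fit on a binary group indicator; returns the hazard ratio
#' `exp(beta)` for group 1 versus group 0 with a Wald 95% confidence interval.
#'
#' @inheritParams logrank_test
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector `c(hr, ci_low, ci_high)`.
#' @export
group_hazard_ratio <- function(outcome, group, conf_level = 0.95) {
  outcome <- as_surv_outcome(outcome)
  group <- as.numeric(as.integer(group))
  fit <- cox_fit(cbind(group = group), outcome)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- fit$coefficients[[1L]]
  se <- fit$standard_errors[[1L]]
  c(hr = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se))
}

#' Pearson chi-square test of association
#'
#' Pearson chi-square on an r x c contingency table, without continuity
#' correction; degrees of freedom `(r - 1)(c - 1)`.
#'
#' @param contingency Matrix of non-negative counts, at least 2 x 2.
#' @return Object of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `expected`.
#' @examples
#' association_test(matrix(c(36, 99, 22, 118), nrow = 2))
#' @export
association_test <- function(contingency) {
  x <- as.matrix(contingency)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least a 2 x 2 table", call. = FALSE)
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(x)
  if (n <= 0) stop("table total must be positive", call. = FALSE)
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero marginal row or column; drop empty levels first", call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  stat <- sum((x - expected)^2 / expected)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df = df, lower.tail = FALSE),
                 expected = expected),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("<chisq> X-squared = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
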