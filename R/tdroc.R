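# Cumulative/dynamic time-dependent ROC at a landmark time, under censoring.
#
# Cases at horizon t are patients with an event by t, controls are patients
# event-free past t. Under censoring the joint distribution of (marker M,
# survival T) is estimated with the smoothed bivariate survivor function
#   S(c, t) = (1/n) sum_i 1[M_i > c] * S_span(t | M = M_i),
# where S_span(t | M = m) is a Kaplan-Meier estimate computed over the
# 2 * span * n patients whose marker percentile is nearest to m (the
# nearest-neighbour estimator, NNE). Then
#   TPR(c) = [(1 - F_M(c)) - S(c, t)] / (1 - S(-Inf, t))
#   FPR(c) = S(c, t) / S(-Inf, t).
# The alternative "KM" weighting estimates S(c, t) as the plain Kaplan-Meier
# within the subgroup M > c times the empirical P(M > c); it reduces exactly
# to the empirical binary ROC of 1[T <= t] when no observation is censored
# before t.

km_at <- function(time, event, t) {
  ut <- sort(unique(time[event == 1L & time <= t]))
  if (!length(ut)) return(1)
  s <- 1
  for (tt in ut) {
    r <- sum(time >= tt)
    d <- sum(time == tt & event == 1L)
    s <- s * (1 - d / r)
  }
  s
}

#' Time-dependent ROC curve at a landmark time
#'
#' Cumulative/dynamic ROC for a continuous risk marker against a
#' right-censored outcome: at horizon `landmark_t`, cases are patients with
#' an event by `landmark_t` and controls are patients event-free past it.
#' Censoring is handled through a smoothed estimate of the bivariate survivor
#' function of (marker, time): the nearest-neighbour estimator (`"nne"`,
#' default), a weighted Kaplan-Meier over each patient's `2 * span * n`
#' nearest marker percentiles, or the subgroup Kaplan-Meier estimator
#' (`"km"`). Sensitivities and specificities are clipped to `[0, 1]` and the
#' curve made monotone; the AUC is the trapezoidal area over the empirical
#' threshold set with (0,0) and (1,1) anchors.
#'
#' @param scores Numeric risk marker per patient (higher = higher risk),
#'   typically the cross-validated risk scores of [loocv_risk_scores()].
#' @param outcome A [surv_outcome] aligned with `scores`.
#' @param landmark_t Landmark time in months (default 36).
#' @param span Nearest-neighbour smoothing fraction in (0, 0.5], or
#'   `"auto"` for `0.25 * n^(-0.2)`.
#' @param estimator `"nne"` or `"km"`.
#' @return Object of class `roc_result`: `landmark_t`, `thresholds`
#'   (ascending), `fpr`, `tpr`, `auc`, `estimator`, `span_used`.
#' @examples
#' oc <- surv_outcome(c(10, 20, 40, 60), c(1, 1, 0, 0))
#' roc_at_time(-oc$time, oc, landmark_t = 36, estimator = "km")$auc
#' @export
roc_at_time <- function(scores, outcome, landmark_t = 36, span = "auto",
                        estimator = c("nne", "km")) {
  estimator <- match.arg(estimator)
  outcome <- as_surv_outcome(outcome)
  if (length(scores) != length(outcome)) {
    stop("`scores` length must match the outcome", call. = FALSE)
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("`scores` must be finite", call. = FALSE)
  }
  if (landmark_t <= 0) stop("`landmark_t` must be positive", call. = FALSE)
  n <- length(scores)
  time <- outcome$time
  event <- outcome$event
  if (!any(event == 1L & time <= landmark_t)) {
    stop("no events observed by the landmark time", call. = FALSE)
  }

  if (length(unique(scores)) == 1L) {
    warning("all scores identical; ROC is the diagonal, AUC = 0.5")
    return(structure(list(landmark_t = landmark_t,
                          thresholds = unique(scores),
                          fpr = c(0, 1), tpr = c(0, 1), auc = 0.5,
                          estimator = estimator, span_used = NA_real_),
                     class = "roc_result"))
  }

  span_used <- NA_real_
  thresholds <- sort(unique(scores))
  if (estimator == "nne") {
    if (identical(span, "auto")) span <- 0.25 * n^(-0.2)
    if (!is.numeric(span) || span <= 0 || span > 0.5) {
      stop("`span` must be in (0, 0.5] or \"auto\"", call. = FALSE)
    }
    span_used <- span
    pct <- rank(scores, ties.method = "average") / n
    # S_span(t | M_i): KM over the marker-percentile neighbourhood of i
    s_cond <- vapply(seq_len(n), function(i) {
      nb <- which(abs(pct - pct[i]) <= span)
      km_at(time[nb], event[nb], landmark_t)
    }, numeric(1))
    s_marg <- mean(s_cond)
    joint <- vapply(thresholds, function(c) mean((scores > c) * s_cond), numeric(1))
    surv_gt <- vapply(thresholds, function(c) mean(scores > c), numeric(1))
    tpr <- (surv_gt - joint) / (1 - s_marg)
    fpr <- joint / s_marg
  } else {
    s_marg <- km_at(time, event, landmark_t)
    joint <- vapply(thresholds, function(c) {
      sel <- scores > c
      if (!any(sel)) return(0)
      mean(sel) * km_at(time[sel], event[sel], landmark_t)
    }, numeric(1))
    surv_gt <- vapply(thresholds, function(c) mean(scores > c), numeric(1))
    tpr <- (surv_gt - joint) / (1 - s_marg)
    fpr <- joint / s_marg
  }

  tpr <- pmin(pmax(tpr, 0), 1)
  fpr <- pmin(pmax(fpr, 0), 1)
  # enforce monotone non-increasing in the threshold
  for (k in seq_len(length(thresholds) - 1L)) {
    tpr[k + 1L] <- min(tpr[k + 1L], tpr[k])
    fpr[k + 1L] <- min(fpr[k + 1L], fpr[k])
  }

  fpr_c <- c(1, fpr, 0)
  tpr_c <- c(1, tpr, 0)
  ord <- order(fpr_c, tpr_c)
  auc <- sum(diff(fpr_c[ord]) * (utils::head(tpr_c[ord], -1) + utils::tail(tpr_c[ord], -1)) / 2)

  structure(list(landmark_t = landmark_t, thresholds = thresholds,
                 fpr = fpr, tpr = tpr, auc = auc, estimator = estimator,
                 span_used = span_used),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> landmark t = %g months, %s estimator, AUC = %.4f\n",
              x$landmark_t, toupper(x$estimator), x$auc))
  invisible(x)
}

#' @export
as.data.frame.roc_result <- function(x, ...) {
  data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
}

#' Time-dependent AUC over a grid of horizons
#'
#' [roc_at_time()] evaluated at each grid time; used to compare the
#' genes-only and combined score vectors along follow-up. Grid points with no
#' prior event are skipped with a warning and reported as `NA`.
#'
#' @inheritParams roc_at_time
#' @param t_grid Increasing vector of horizons (months).
#' @return data.frame with columns `t` and `auc`.
#' @export
auc_over_time <- function(scores, outcome, t_grid, span = "auto",
                          estimator = c("nne", "km")) {
  estimator <- match.arg(estimator)
  outcome <- as_surv_outcome(outcome)
  auc <- vapply(t_grid, function(t) {
    if (!any(outcome$event == 1L & outcome$time <= t)) {
      warning(sprintf("no events by t = %g; AUC undefined there", t))
      return(NA_real_)
    }
    suppressWarnings(
      roc_at_time(scores, outcome, landmark_t = t, span = span,
                  estimator = estimator)$auc)
  }, numeric(1))
  data.frame(t = t_grid, auc = auc)
}
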