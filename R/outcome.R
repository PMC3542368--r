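#' Right-censored survival outcome
#'
#' Container for one endpoint (overall survival or progression-free survival):
#' per-patient follow-up time in months and an event indicator.
#'
#' @param time Numeric vector of positive, finite follow-up times (months).
#' @param event Event indicator per patient: 1 = event (death for OS,
#'   progression for PFS), 0 = right-censored. Logicals are accepted.
#' @param patient_id Optional character vector of patient identifiers.
#'
#' @return An object of class `surv_outcome`: a list with elements `time`,
#'   `event` and `patient_id`.
#' @examples
#' surv_outcome(c(12, 30.5, 48), c(1, 0, 1))
#' @export
surv_outcome <- function(time, event, patient_id = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(event)) {
    stop("`time` and `event` must have the same length", call. = FALSE)
  }
  if (length(time) < 1L) stop("outcome must contain at least one patient", call. = FALSE)
  if (anyNA(time) || any(!is.finite(time))) {
    stop("`time` must be finite and non-missing", call. = FALSE)
  }
  if (any(time <= 0)) stop("`time` must be strictly positive", call. = FALSE)
  if (anyNA(event) || !all(event %in% c(0L, 1L))) {
    stop("`event` must be 0/1 with no missing values", call. = FALSE)
  }
  if (!is.null(patient_id) && length(patient_id) != length(time)) {
    stop("`patient_id` length must match `time`", call. = FALSE)
  }
  structure(list(time = time, event = event,
                 patient_id = if (is.null(patient_id)) NULL else as.character(patient_id)),
            class = "surv_outcome")
}

#' @export
length.surv_outcome <- function(x) length(x$time)

#' @export
`[.surv_outcome` <- function(x, i) {
  surv_outcome(x$time[i], x$event[i],
               if (is.null(x$patient_id)) NULL else x$patient_id[i])
}

#' @export
print.surv_outcome <- function(x, ...) {
  cat(sprintf("<surv_outcome> %d patients, %d events (%.1f%%), median follow-up %.1f months\n",
              length(x), sum(x$event), 100 * mean(x$event), median(x$time)))
  invisible(x)
}

as_surv_outcome <- function(x) {
  if (inherits(x, "surv_outcome")) return(x)
  stop("expected a `surv_outcome` object; see surv_outcome()", call. = FALSE)
}
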