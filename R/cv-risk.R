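#' Screen genes by two-group log-rank test
#'
#' Tests each gene (mutated vs. wild-type) with the two-group log-rank test
#' and returns the genes with p-value below `alpha`, sorted by p-value.
#' Genes for which one group is empty (all-zero or all-one columns) are not
#' testable and are skipped.
#'
#' @param matrix Patients x genes binary matrix, aligned with `outcome`.
#' @param outcome A [surv_outcome].
#' @param alpha Per-gene screening threshold in (0, 1); default 0.01.
#' @return data.frame with columns `gene`, `statistic`, `p_value`, sorted by
#'   increasing p-value (possibly zero rows).
#' @export
select_genes <- function(matrix, outcome, alpha = 0.01) {
  check_mutation_matrix(matrix)
  outcome <- as_surv_outcome(outcome)
  if (nrow(matrix) != length(outcome)) {
    stop("matrix rows must match the outcome length", call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  if (ncol(matrix) == 0L) {
    return(data.frame(gene = character(0), statistic = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  storage.mode(matrix) <- "integer"
  sc <- logrank_screen_cpp(matrix, outcome$time, outcome$event)
  p <- pchisq(sc$statistic, df = 1, lower.tail = FALSE)
  sel <- which(!is.na(p) & p < alpha)
  out <- data.frame(gene = colnames(matrix)[sel], statistic = sc$statistic[sel],
                    p_value = p[sel], stringsAsFactors = FALSE)
  out[order(out$p_value), , drop = FALSE]
}

#' Standardize values with training-set mean and standard deviation
#'
#' Centers and scales `apply_values` by the mean and sample standard
#' deviation (n - 1 denominator) of `train_values`, the transformation used
#' for gene columns inside each cross-validation fold.
#'
#' @param train_values Numeric vector the location/scale are estimated from.
#' @param apply_values Numeric vector to transform (defaults to
#'   `train_values`).
#' @return List with `values` (standardized `apply_values`), `mean`, `sd`.
#' @examples
#' standardize(c(0, 0, 1, 1))$values
#' @export
standardize <- function(train_values, apply_values = train_values) {
  m <- mean(train_values)
  s <- sd(train_values)
  if (!is.finite(s) || s == 0) {
    stop("training values have zero standard deviation", call. = FALSE)
  }
  list(values = (apply_values - m) / s, mean = m, sd = s)
}

clinical_indicator_matrix <- function(clinical) {
  cbind(age_gt60 = as.numeric(clinical$age_gt60 == 1L),
        grade3 = as.numeric(clinical$grade == 3L),
        stage4 = as.numeric(clinical$stage == 4L),
        macroscopic = as.numeric(clinical$residual == "macroscopic"))
}

#' Leave-one-out cross-validated risk scores
#'
#' Complete leave-one-out cross-validation of the mutation-signature risk
#' model. For each patient i the model is rebuilt from scratch on the other
#' n - 1 patients: genes are re-screened by log-rank test at level `alpha`,
#' the selected gene columns are standardized by their training mean and
#' standard deviation, a multivariate Cox model is fitted to the standardized
#' genes, and patient i's risk score is the Cox linear predictor of their
#' standardized mutation profile. After all n folds the scores are
#' dichotomized at their median (score strictly above the median = high risk)
#' and the two cross-validated risk groups are compared by log-rank test.
#'
#' Out-of-fold linear predictors from different folds are not directly
#' comparable: the fold-specific centering term shared by all patients
#' carrying none of that fold's genes tracks the held-out patient's own
#' outcome, which can scramble or even invert a split taken on the raw pooled
#' values. Each held-out score is therefore reported centered at the median
#' of its fold's training-set scores, which places all n scores on a common
#' "distance from the training median" scale; the median split and the
#' time-dependent ROC use these centered scores. The raw linear predictors
#' are kept in `scores_raw`.
#'
#' Folds in which no gene passes the screen score 0 (the empty linear
#' predictor) so that all n patients keep a score. When `clinical` is
#' supplied, four binary clinicopathological indicators (age > 60, grade 3,
#' stage 4, macroscopic residual) are forced, unstandardized, into every
#' fold's Cox model alongside the selected genes (the combined model);
#' patients missing any of the four are excluded first (complete-case), and
#' empty-selection folds then score with the clinical-only model.
#'
#' Per-fold Cox non-convergence (e.g. monotone likelihood on a sparse gene)
#' is counted and warned about, never an error: the fold's fitted
#' coefficients are still used.
#'
#' @inheritParams select_genes
#' @param clinical Optional clinical data.frame (see [read_clinical()]); when
#'   provided the combined genes + clinical model is cross-validated.
#' @param ties Cox tie handling, `"efron"` (default) or `"breslow"`.
#' @param min_n Minimum cohort size (guard against meaningless folds).
#' @return Object of class `cv_result`: `scores` (per patient, fold-centered),
#'   `scores_raw` (uncentered linear predictors), `cutoff`
#'   (median score), `risk_group` (factor low/high), `cv_logrank`
#'   ([logrank_test] of the risk groups; NA with a warning if one group is
#'   empty), `selection_frequency` (named count of folds selecting each ever-
#'   selected gene), `per_fold_models` (list of per-fold gene sets, means,
#'   sds and coefficients), `outcome`, `n_empty_folds`, `n_nonconverged`,
#'   `combined` flag and `patient_id`.
#' @export
loocv_risk_scores <- function(matrix, outcome, alpha = 0.01, clinical = NULL,
                              ties = c("efron", "breslow"), min_n = 20L) {
  ties <- match.arg(ties)
  check_mutation_matrix(matrix)
  outcome <- as_surv_outcome(outcome)
  if (nrow(matrix) != length(outcome)) {
    stop("matrix rows must match the outcome length", call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)

  Z <- NULL
  kept <- seq_len(nrow(matrix))
  if (!is.null(clinical)) {
    if (nrow(clinical) != nrow(matrix)) {
      stop("`clinical` must have one row per matrix row", call. = FALSE)
    }
    Zfull <- clinical_indicator_matrix(clinical)
    complete <- stats::complete.cases(Zfull)
    if (!all(complete)) {
      message(sprintf("combined model: excluding %d patient(s) with missing clinical covariates",
                      sum(!complete)))
    }
    kept <- which(complete)
    matrix <- matrix[kept, , drop = FALSE]
    outcome <- outcome[kept]
    Z <- Zfull[kept, , drop = FALSE]
  }
  n <- nrow(matrix)
  if (n < min_n) {
    stop(sprintf("need at least %d patients for leave-one-out cross-validation", min_n),
         call. = FALSE)
  }
  storage.mode(matrix) <- "integer"

  res <- loocv_cpp(matrix, outcome$time, outcome$event, alpha, Z,
                   efron = ties == "efron", keep_folds = TRUE)
  scores <- as.numeric(res$scores)
  scores_raw <- as.numeric(res$scores_raw)
  cutoff <- median(scores)
  risk_group <- factor(ifelse(scores > cutoff, "high", "low"),
                       levels = c("low", "high"))

  cv_lr <- NULL
  if (all(risk_group == "low") || all(risk_group == "high")) {
    warning("all cross-validated scores fall on one side of the median; log-rank undefined")
  } else {
    cv_lr <- logrank_test(outcome, as.integer(risk_group == "high"))
  }
  if (res$n_nonconverged > 0) {
    warning(sprintf("%d fold(s) flagged Cox non-convergence", res$n_nonconverged))
  }

  sel_count <- as.integer(res$selection_count)
  names(sel_count) <- colnames(matrix)
  folds <- lapply(res$folds, function(f) {
    f$genes <- colnames(matrix)[f$genes]
    names(f$coef_clinical) <- colnames(Z)
    if (is.null(Z)) f$coef_clinical <- NULL
    f
  })

  structure(list(scores = scores, scores_raw = scores_raw, cutoff = cutoff,
                 risk_group = risk_group,
                 cv_logrank = cv_lr,
                 selection_frequency = sel_count[sel_count > 0],
                 per_fold_models = folds, outcome = outcome,
                 n_empty_folds = res$n_empty_folds,
                 n_nonconverged = res$n_nonconverged,
                 combined = !is.null(Z), alpha = alpha, ties = ties,
                 patient_id = rownames(matrix), kept = kept),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> n = %d (%s model), %d/%d low/high risk, %d empty fold(s)\n",
              length(x$scores), if (x$combined) "combined" else "genes-only",
              sum(x$risk_group == "low"), sum(x$risk_group == "high"),
              x$n_empty_folds))
  if (!is.null(x$cv_logrank)) {
    cat(sprintf("  cross-validated log-rank: chisq = %.4g, p = %.4g\n",
                x$cv_logrank$statistic, x$cv_logrank$p_value))
  }
  invisible(x)
}

#' Fit the final full-data risk model
#'
#' Single pass on the full cohort: screen genes by log-rank at level `alpha`,
#' standardize the selected columns, fit the multivariate Cox model (with the
#' four clinical indicators forced in when `clinical` is given), and report
#' per-gene screening p-value and Cox coefficient.
#'
#' @inheritParams loocv_risk_scores
#' @return Object of class `risk_model`: `genes`, `means`, `sds`,
#'   `coefficients`, `gene_table` (data.frame gene / p_value / coefficient),
#'   `clinical_terms` (named coefficients or NULL), `fit` (the [cox_fit]) and
#'   `alpha`. When no gene passes the screen, an empty model with a warning.
#' @export
fit_final_model <- function(matrix, outcome, alpha = 0.01, clinical = NULL,
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_mutation_matrix(matrix)
  outcome <- as_surv_outcome(outcome)
  Z <- NULL
  if (!is.null(clinical)) {
    Zfull <- clinical_indicator_matrix(clinical)
    complete <- stats::complete.cases(Zfull)
    matrix <- matrix[complete, , drop = FALSE]
    outcome <- outcome[which(complete)]
    Z <- Zfull[complete, , drop = FALSE]
  }
  sel <- select_genes(matrix, outcome, alpha)
  if (nrow(sel) == 0L && is.null(Z)) {
    warning("no genes selected at alpha = ", alpha, "; returning an empty model")
    return(structure(list(genes = character(0), means = numeric(0),
                          sds = numeric(0), coefficients = numeric(0),
                          gene_table = data.frame(gene = character(0),
                                                  p_value = numeric(0),
                                                  coefficient = numeric(0)),
                          clinical_terms = NULL, fit = NULL, alpha = alpha),
                     class = "risk_model"))
  }
  Xs <- NULL
  means <- sds <- numeric(0)
  if (nrow(sel) > 0L) {
    sub <- matrix[, sel$gene, drop = FALSE]
    means <- colMeans(sub)
    sds <- apply(sub, 2L, sd)
    Xs <- scale(sub, center = means, scale = sds)
  }
  W <- cbind(Xs, Z)
  fit <- cox_fit(W, outcome, ties = ties)
  k <- nrow(sel)
  structure(list(genes = sel$gene, means = means, sds = sds,
                 coefficients = if (k) setNames(fit$coefficients[seq_len(k)], sel$gene)
                                else numeric(0),
                 gene_table = data.frame(gene = sel$gene, p_value = sel$p_value,
                                         coefficient = if (k) unname(fit$coefficients[seq_len(k)])
                                                       else numeric(0),
                                         stringsAsFactors = FALSE),
                 clinical_terms = if (!is.null(Z)) fit$coefficients[k + seq_len(ncol(Z))]
                                  else NULL,
                 fit = fit, alpha = alpha),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d gene(s)%s\n", length(x$genes),
              if (!is.null(x$clinical_terms)) " + 4 clinical terms" else ""))
  if (nrow(x$gene_table)) print(x$gene_table, row.names = FALSE)
  invisible(x)
}

#' Score patients with a fitted risk model
#'
#' @param object A [fit_final_model] result.
#' @param matrix Patients x genes matrix containing the model's genes.
#' @param clinical Clinical data.frame, required when the model has clinical
#'   terms.
#' @param ... Unused.
#' @return Numeric risk score per patient.
#' @export
predict.risk_model <- function(object, matrix, clinical = NULL, ...) {
  score <- numeric(nrow(matrix))
  if (length(object$genes)) {
    miss <- setdiff(object$genes, colnames(matrix))
    if (length(miss)) {
      stop(sprintf("matrix lacks model gene(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    Xs <- scale(matrix[, object$genes, drop = FALSE],
                center = object$means, scale = object$sds)
    score <- score + as.numeric(Xs %*% object$coefficients)
  }
  if (!is.null(object$clinical_terms)) {
    if (is.null(clinical)) stop("model has clinical terms; `clinical` required",
                                call. = FALSE)
    Z <- clinical_indicator_matrix(clinical)
    score <- score + as.numeric(Z %*% object$clinical_terms)
  }
  score
}

#' Gene selection frequencies across cross-validation folds
#'
#' Counts, for each gene ever selected, the number of leave-one-out folds in
#' which it entered the model — the stability report accompanying the final
#' gene table. (A gene selected in nearly every one of n folds indicates a
#' stable signature member.)
#'
#' @param cv A [loocv_risk_scores] result.
#' @return data.frame with columns `gene`, `folds_selected`, sorted by
#'   decreasing frequency; genes never selected are absent.
#' @export
selection_frequency_report <- function(cv) {
  if (!inherits(cv, "cv_result")) stop("`cv` must be a cv_result", call. = FALSE)
  sf <- cv$selection_frequency
  out <- data.frame(gene = names(sf), folds_selected = as.integer(sf),
                    stringsAsFactors = FALSE)
  out[order(-out$folds_selected, out$gene), , drop = FALSE]
}
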