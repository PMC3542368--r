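#' Configuration for an end-to-end pipeline run
#'
#' Exactly one input source: either `sim` (a [sim_config], the cohort is
#' generated) or `maf` + `clinical` file paths.
#'
#' @param endpoint `"OS"` or `"PFS"`.
#' @param sim Optional [sim_config].
#' @param maf,clinical Optional paths to a MAF-dialect mutation file and a
#'   clinical TSV (see [read_maf()], [read_clinical()]).
#' @param alpha Per-gene log-rank screening threshold.
#' @param min_mutated_patients Rare-gene filter threshold.
#' @param B Number of permutations for the permutation p-value (0 skips it).
#' @param landmark_t Landmark time for the ROC (months).
#' @param span,estimator Passed to [roc_at_time()].
#' @param t_grid Horizon grid for the AUC-versus-time comparison; defaults to
#'   12 to 60 months by 6.
#' @param combined Also run the combined genes + clinical model and the
#'   AUC(t) comparison (default `TRUE`).
#' @param seed Integer seed (mandatory).
#' @return Object of class `run_config`.
#' @export
run_config <- function(endpoint = c("OS", "PFS"), sim = NULL, maf = NULL,
                       clinical = NULL, alpha = 0.01, min_mutated_patients = 5L,
                       B = 100L, landmark_t = 36, span = "auto",
                       estimator = c("nne", "km"),
                       t_grid = seq(12, 60, by = 6), combined = TRUE, seed) {
  endpoint <- match.arg(endpoint)
  estimator <- match.arg(estimator)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  has_sim <- !is.null(sim)
  has_files <- !is.null(maf) || !is.null(clinical)
  if (has_sim == has_files) {
    stop("provide exactly one of `sim` or (`maf` + `clinical`)", call. = FALSE)
  }
  if (has_files && (is.null(maf) || is.null(clinical))) {
    stop("file input needs both `maf` and `clinical`", call. = FALSE)
  }
  if (has_sim && !inherits(sim, "sim_config")) {
    stop("`sim` must come from sim_config()", call. = FALSE)
  }
  structure(list(endpoint = endpoint, sim = sim, maf = maf, clinical = clinical,
                 alpha = alpha, min_mutated_patients = as.integer(min_mutated_patients),
                 B = as.integer(B), landmark_t = landmark_t, span = span,
                 estimator = estimator, t_grid = t_grid,
                 combined = isTRUE(combined), seed = as.integer(seed)),
            class = "run_config")
}

# Table-2-style association of the risk groups with each clinical factor.
association_table <- function(clinical, risk_group) {
  vars <- list(age = factor(clinical$age_gt60, levels = c(0L, 1L),
                            labels = c("<=60", ">60")),
               surgical = factor(clinical$residual,
                                 levels = c("microscopic", "macroscopic")),
               platinum = factor(clinical$platinum,
                                 levels = c("sensitive", "resistant")),
               grade = factor(clinical$grade, levels = c(2L, 3L)),
               stage = factor(clinical$stage, levels = c(2L, 3L, 4L)))
  rows <- lapply(names(vars), function(v) {
    f <- vars[[v]]
    ok <- !is.na(f)
    tab <- table(f[ok], risk_group[ok])
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    p <- if (nrow(tab) >= 2L && all(colSums(tab) > 0)) {
      association_test(unclass(tab))$p_value
    } else NA_real_
    data.frame(variable = v, level = rownames(tab),
               n_low = as.integer(tab[, "low"]), n_high = as.integer(tab[, "high"]),
               p_value = c(p, rep(NA_real_, nrow(tab) - 1L)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full prognostic-modeling pipeline
#'
#' Executes every stage on one endpoint: read or simulate the cohort, filter
#' rare genes, align mutation/clinical/outcome tables, run the complete
#' leave-one-out cross-validation (genes-only and, optionally, combined with
#' clinical covariates), the permutation p-value, cross-validated
#' Kaplan-Meier curves per risk group, the landmark time-dependent ROC, the
#' AUC-versus-time comparison, the final full-data model with gene selection
#' frequencies, and the risk-group x clinical association table. Fully
#' deterministic given the configuration.
#'
#' @param config A [run_config].
#' @param out_dir Optional directory; when given, the tables are written as
#'   CSV/JSON together with a `manifest.json` capturing every parameter.
#' @return Object of class `run_bundle`: list with `cv`, `cv_combined`,
#'   `permutation`, `km` (per risk group), `roc`, `auc_t`, `final_model`,
#'   `selection_frequency`, `association`, `hazard_ratio`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) stop("`config` must come from run_config()",
                                            call. = FALSE)
  if (!is.null(config$sim)) {
    cohort <- generate_cohort(config$sim)
    mat <- cohort$mutations
    clin <- cohort$clinical
  } else {
    mat <- read_maf(config$maf)
    clin <- read_clinical(config$clinical)
  }
  mat <- filter_rare_genes(mat, config$min_mutated_patients)
  al <- align_cohort(mat, clin, endpoint = config$endpoint)

  cv <- loocv_risk_scores(al$mutations, al$outcome, alpha = config$alpha)
  grp <- cv$risk_group
  km <- list(low = km_estimate(al$outcome[grp == "low"]),
             high = km_estimate(al$outcome[grp == "high"]))
  hr <- group_hazard_ratio(al$outcome, as.integer(grp == "high"))
  perm <- if (config$B > 0) {
    permutation_pvalue(al$mutations, al$outcome, alpha = config$alpha,
                       B = config$B, seed = config$seed)
  } else NULL
  roc <- roc_at_time(cv$scores, al$outcome, landmark_t = config$landmark_t,
                     span = config$span, estimator = config$estimator)
  auc_t <- auc_over_time(cv$scores, al$outcome, config$t_grid,
                         span = config$span, estimator = config$estimator)
  names(auc_t)[2] <- "auc_genes"

  cv_comb <- NULL
  if (config$combined) {
    cv_comb <- loocv_risk_scores(al$mutations, al$outcome, alpha = config$alpha,
                                 clinical = al$clinical)
    auc_comb <- auc_over_time(cv_comb$scores, cv_comb$outcome, config$t_grid,
                              span = config$span, estimator = config$estimator)
    auc_t$auc_combined <- auc_comb$auc
  }

  final <- fit_final_model(al$mutations, al$outcome, alpha = config$alpha)
  sf <- selection_frequency_report(cv)

  bundle <- structure(list(cv = cv, cv_combined = cv_comb, permutation = perm,
                           km = km, roc = roc, auc_t = auc_t,
                           final_model = final, selection_frequency = sf,
                           association = association_table(al$clinical, grp),
                           hazard_ratio = hr, config = config),
                      class = "run_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  cat(sprintf("<run_bundle> endpoint %s, n = %d\n", x$config$endpoint,
              length(x$cv$scores)))
  cat(sprintf("  median survival: low-risk %s, high-risk %s months; HR (high vs low) %.3f\n",
              formatC(x$km$low$median, digits = 3, format = "fg"),
              formatC(x$km$high$median, digits = 3, format = "fg"),
              x$hazard_ratio[["hr"]]))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation p = %.4g (B = %d)\n", x$permutation$p_value,
                x$permutation$B))
  }
  cat(sprintf("  landmark AUC(t = %g) = %.3f\n", x$roc$landmark_t, x$roc$auc))
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) write.csv(df, file.path(out_dir, name), row.names = FALSE)
  cv <- bundle$cv
  w(data.frame(patient_id = cv$patient_id, score = cv$scores,
               group = as.character(cv$risk_group)), "scores.csv")
  if (!is.null(bundle$cv_combined)) {
    cvc <- bundle$cv_combined
    w(data.frame(patient_id = cvc$patient_id, score = cvc$scores,
                 group = as.character(cvc$risk_group)), "scores_combined.csv")
  }
  gene_tab <- bundle$final_model$gene_table
  gene_tab$frequency <- bundle$cv$selection_frequency[gene_tab$gene]
  w(gene_tab[, c("gene", "p_value", "frequency", "coefficient")], "gene_report.csv")
  km_df <- do.call(rbind, lapply(names(bundle$km), function(g) {
    df <- as.data.frame(bundle$km[[g]])
    if (nrow(df)) cbind(group = g, df) else NULL
  }))
  w(km_df, "km.csv")
  w(as.data.frame(bundle$roc), "roc.csv")
  w(bundle$auc_t, "auc_t.csv")
  w(bundle$association, "association.csv")

  results <- list(
    endpoint = bundle$config$endpoint,
    n_patients = length(cv$scores),
    cutoff = cv$cutoff,
    cv_logrank_statistic = cv$cv_logrank$statistic,
    cv_logrank_p_naive = cv$cv_logrank$p_value,
    permutation_p = if (!is.null(bundle$permutation)) bundle$permutation$p_value else NULL,
    median_low = bundle$km$low$median, median_low_ci = unname(bundle$km$low$median_ci),
    median_high = bundle$km$high$median, median_high_ci = unname(bundle$km$high$median_ci),
    hazard_ratio = unname(bundle$hazard_ratio),
    landmark_t = bundle$roc$landmark_t,
    auc = bundle$roc$auc)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cfg <- bundle$config
  manifest <- list(package = "mutsurv",
                   version = as.character(utils::packageVersion("mutsurv")),
                   endpoint = cfg$endpoint, alpha = cfg$alpha,
                   min_mutated_patients = cfg$min_mutated_patients, B = cfg$B,
                   landmark_t = cfg$landmark_t, span = cfg$span,
                   estimator = cfg$estimator, t_grid = cfg$t_grid,
                   combined = cfg$combined, seed = cfg$seed,
                   sim = if (!is.null(cfg$sim)) unclass(cfg$sim) else NULL,
                   maf = cfg$maf, clinical = cfg$clinical)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
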