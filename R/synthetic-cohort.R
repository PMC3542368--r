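#' Simulation configuration for a synthetic mutation cohort
#'
#' Describes a cohort with the statistical structure the risk-model pipeline
#' assumes: a sparse patients x genes binary mutation matrix, exponential
#' survival from a proportional-hazards model driven by a small set of causal
#' genes, independent exponential censoring truncated at an administrative
#' follow-up limit, and categorical clinical covariates.
#'
#' Defaults emulate a cohort of advanced ovarian high-grade serous carcinoma
#' at desk scale: ~300 patients, per-gene mutation frequencies between 2% and
#' 15% (so the rare-gene filter at 5 patients is satisfiable), a baseline
#' hazard giving a median overall survival near 42 months, and censoring
#' yielding roughly 55-60% observed events within a 120-month follow-up
#' window. Progression-free survival uses the same linear predictor with the
#' baseline time scale shrunk by `pfs_time_scale`.
#'
#' @param n_patients Number of patients (>= 2).
#' @param n_genes Number of genes.
#' @param causal_genes Number of genes with a true effect (<= `n_genes`).
#' @param causal_log_hr Per-causal-gene log hazard ratio; scalar or a vector
#'   of length `causal_genes`.
#' @param mutation_freq_range Length-2 range in (0, 1); each gene's mutation
#'   probability is drawn uniformly from it.
#' @param baseline_hazard Baseline event rate per month (> 0).
#' @param censor_rate Censoring rate per month (>= 0; 0 = administrative
#'   censoring only).
#' @param max_followup Administrative follow-up limit in months (may be Inf).
#' @param pfs_time_scale Multiplier (< 1 shortens) applied to the PFS time
#'   scale relative to OS.
#' @param clinical_missing_rate Probability each clinical covariate value is
#'   missing (missing completely at random).
#' @param residual_confounding Log-odds shift of macroscopic residual disease
#'   per unit of the (centered) genetic linear predictor; 0 (default) makes
#'   clinical covariates independent of the genes.
#' @param seed Integer seed; mandatory, the cohort is fully reproducible from
#'   the configuration.
#'
#' @return Object of class `sim_config` (a validated list).
#' @examples
#' sim_config(n_patients = 100, n_genes = 50, seed = 1)
#' @export
sim_config <- function(n_patients = 300L, n_genes = 200L, causal_genes = 5L,
                       causal_log_hr = 1.0,
                       mutation_freq_range = c(0.02, 0.15),
                       baseline_hazard = 1 / 60, censor_rate = 1 / 90,
                       max_followup = 120, pfs_time_scale = 0.4,
                       clinical_missing_rate = 0.03,
                       residual_confounding = 0, seed) {
  if (missing(seed)) stop("`seed` is mandatory in sim_config()", call. = FALSE)
  stopifnot_scalar(n_patients, "n_patients", positive = TRUE)
  stopifnot_scalar(n_genes, "n_genes", positive = TRUE)
  stopifnot_scalar(causal_genes, "causal_genes")
  if (n_patients < 2) stop("`n_patients` must be at least 2", call. = FALSE)
  if (causal_genes < 0 || causal_genes > n_genes) {
    stop("`causal_genes` must be between 0 and `n_genes`", call. = FALSE)
  }
  if (any(!is.finite(causal_log_hr))) {
    stop("`causal_log_hr` must be finite", call. = FALSE)
  }
  if (causal_genes > 0 && !(length(causal_log_hr) %in% c(1L, causal_genes))) {
    stop("`causal_log_hr` must have length 1 or `causal_genes`", call. = FALSE)
  }
  if (length(mutation_freq_range) != 2L || any(mutation_freq_range <= 0) ||
      any(mutation_freq_range >= 1) ||
      mutation_freq_range[1] > mutation_freq_range[2]) {
    stop("`mutation_freq_range` must be an increasing pair within (0, 1)",
         call. = FALSE)
  }
  stopifnot_scalar(baseline_hazard, "baseline_hazard", positive = TRUE)
  if (!is.numeric(censor_rate) || censor_rate < 0) {
    stop("`censor_rate` must be >= 0", call. = FALSE)
  }
  if (max_followup <= 0) stop("`max_followup` must be positive", call. = FALSE)
  stopifnot_scalar(pfs_time_scale, "pfs_time_scale", positive = TRUE)
  if (clinical_missing_rate < 0 || clinical_missing_rate >= 1) {
    stop("`clinical_missing_rate` must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes),
                 causal_genes = as.integer(causal_genes),
                 causal_log_hr = as.numeric(causal_log_hr),
                 mutation_freq_range = as.numeric(mutation_freq_range),
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, max_followup = max_followup,
                 pfs_time_scale = pfs_time_scale,
                 clinical_missing_rate = clinical_missing_rate,
                 residual_confounding = residual_confounding,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_endpoint <- function(n, rate0, lp, censor_rate, max_followup) {
  t_event <- rexp(n, rate = rate0 * exp(lp))
  t_cens <- if (censor_rate > 0) pmin(rexp(n, rate = censor_rate), max_followup)
            else rep(max_followup, n)
  time <- pmin(t_event, t_cens)
  list(time = time, event = as.integer(t_event <= t_cens))
}

#' Generate a synthetic mutation cohort
#'
#' Draws a cohort from a [sim_config]: independent per-gene Bernoulli
#' mutations, exponential OS and PFS times under a proportional-hazards model
#' over the causal genes, independent exponential censoring truncated at the
#' follow-up limit, and categorical clinical covariates (age group, grade,
#' stage, surgical residual, platinum status) with MCAR missingness.
#'
#' @param config A [sim_config].
#' @return Object of class `synthetic_cohort`: list with `mutations`
#'   (patients x genes binary matrix), `os` and `pfs` ([surv_outcome]),
#'   `clinical` (data.frame, one row per patient), `truth` (data.frame of
#'   causal genes and their log hazard ratios) and `config`.
#' @examples
#' ch <- generate_cohort(sim_config(n_patients = 50, n_genes = 20, seed = 7))
#' dim(ch$mutations)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must come from sim_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    n <- config$n_patients
    G <- config$n_genes
    patient_id <- sprintf("TCGA-SY-%04d", seq_len(n))
    genes <- sprintf("GENE%04d", seq_len(G))

    p_gene <- runif(G, config$mutation_freq_range[1], config$mutation_freq_range[2])
    X <- matrix(rbinom(n * G, 1L, rep(p_gene, each = n)), nrow = n,
                dimnames = list(patient_id, genes))

    causal_idx <- if (config$causal_genes > 0) sort(sample.int(G, config$causal_genes)) else integer(0)
    beta <- rep(config$causal_log_hr, length.out = config$causal_genes)
    lp <- if (length(causal_idx)) as.numeric(X[, causal_idx, drop = FALSE] %*% beta)
          else numeric(n)

    os <- sim_endpoint(n, config$baseline_hazard, lp, config$censor_rate,
                       config$max_followup)
    pfs <- sim_endpoint(n, config$baseline_hazard / config$pfs_time_scale, lp,
                        config$censor_rate, config$max_followup)

    age_gt60 <- rbinom(n, 1L, 0.5)
    grade <- sample(c(2L, 3L), n, replace = TRUE, prob = c(0.09, 0.91))
    stage <- sample(c(2L, 3L, 4L), n, replace = TRUE, prob = c(0.045, 0.78, 0.175))
    p_macro <- stats::plogis(stats::qlogis(0.79) +
                             config$residual_confounding * (lp - mean(lp)))
    residual <- ifelse(rbinom(n, 1L, p_macro) == 1L, "macroscopic", "microscopic")
    platinum <- ifelse(rbinom(n, 1L, 0.35) == 1L, "resistant", "sensitive")

    clinical <- data.frame(patient_id = patient_id,
                           os_months = os$time, os_event = os$event,
                           pfs_months = pfs$time, pfs_event = pfs$event,
                           age_gt60 = age_gt60, grade = grade, stage = stage,
                           residual = residual, platinum = platinum,
                           stringsAsFactors = FALSE)
    if (config$clinical_missing_rate > 0) {
      for (col in c("age_gt60", "grade", "stage", "residual", "platinum")) {
        miss <- runif(n) < config$clinical_missing_rate
        clinical[[col]][miss] <- NA
      }
    }

    structure(list(mutations = X,
                   os = surv_outcome(os$time, os$event, patient_id),
                   pfs = surv_outcome(pfs$time, pfs$event, patient_id),
                   clinical = clinical,
                   truth = data.frame(gene = genes[causal_idx],
                                      log_hr = beta,
                                      stringsAsFactors = FALSE),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients x %d genes, %d causal gene(s), OS events %d, PFS events %d\n",
              nrow(x$mutations), ncol(x$mutations), nrow(x$truth),
              sum(x$os$event), sum(x$pfs$event)))
  invisible(x)
}

#' Write a synthetic cohort as MAF-dialect and clinical TSV fixtures
#'
#' Emits one row per (patient, gene) mutation in a minimal Mutation Annotation
#' Format dialect (`Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`, sample barcodes carrying a trailing specimen
#' token so the reader's barcode truncation is exercised) plus a clinical
#' tab-separated table. Both round-trip exactly through [read_maf()] and
#' [read_clinical()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, named character vector with the `maf` and `clinical`
#'   file paths.
#' @export
write_cohort_fixture <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("`cohort` must be a synthetic_cohort", call. = FALSE)
  }
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  maf_path <- file.path(directory, "mutations.maf.tsv")
  clin_path <- file.path(directory, "clinical.tsv")

  idx <- which(cohort$mutations == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  maf <- data.frame(
    Hugo_Symbol = colnames(cohort$mutations)[idx[, "col"]],
    Tumor_Sample_Barcode = paste0(rownames(cohort$mutations)[idx[, "row"]], "-01A"),
    Variant_Classification = "Missense_Mutation",
    stringsAsFactors = FALSE)
  utils::write.table(maf, maf_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, clin_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(maf = maf_path, clinical = clin_path))
}
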