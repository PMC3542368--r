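strong_cohort <- function(seed = 5, n = 300, G = 100) {
  generate_cohort(sim_config(n_patients = n, n_genes = G, causal_genes = 5,
                             causal_log_hr = 1, seed = seed))
}

test_that("gene screening returns sub-threshold genes sorted by p-value", {
  ch <- strong_cohort(seed = 5, n = 200, G = 50)
  sel <- select_genes(ch$mutations, ch$os, alpha = 0.01)
  expect_true(all(sel$p_value < 0.01))
  expect_false(is.unsorted(sel$p_value))
  # screening p-values agree with the single-gene log-rank test
  for (g in sel$gene[seq_len(min(3, nrow(sel)))]) {
    lr <- logrank_test(ch$os, ch$mutations[, g])
    expect_equal(sel$p_value[sel$gene == g], lr$p_value, tolerance = 1e-12)
  }
  # alpha = 1 returns every testable gene
  testable <- colnames(ch$mutations)[colSums(ch$mutations) > 0 &
                                     colSums(ch$mutations) < nrow(ch$mutations)]
  expect_setequal(select_genes(ch$mutations, ch$os, alpha = 1)$gene, testable)
})

test_that("an extreme-separation gene is always selected", {
  set.seed(101)
  n <- 60
  X <- matrix(rbinom(n * 10, 1, 0.2), nrow = n,
              dimnames = list(sprintf("P%02d", 1:n), sprintf("G%02d", 1:10)))
  X[, 1] <- c(rep(1L, 15), rep(0L, n - 15))
  time <- c(sort(rexp(15, 1)), 10 + rexp(n - 15, 0.05))  # mutated all die first
  sel <- select_genes(X, surv_outcome(time, rep(1, n)), alpha = 0.01)
  expect_true("G01" %in% sel$gene)
  expect_lt(sel$p_value[sel$gene == "G01"], 1e-6)
})

test_that("standardization uses the training mean and n-1 standard deviation", {
  v <- c(1, 4, 4, 9, 2)
  st <- standardize(v)
  expect_equal(mean(st$values), 0, tolerance = 1e-12)
  expect_equal(sd(st$values), 1, tolerance = 1e-12)
  # binary closed form
  x <- c(rep(1, 3), rep(0, 7))
  st2 <- standardize(x)
  expect_equal(st2$mean, 0.3)
  expect_equal(st2$sd, sqrt(3 * 7 / (10 * 9)))
  # applying to an all-zero vector gives the constant -mean/sd
  st3 <- standardize(x, rep(0, 4))
  expect_equal(st3$values, rep(-0.3 / st2$sd, 4))
  expect_error(standardize(rep(2, 5)), "zero standard deviation")
})

test_that("LOOCV produces one leakage-free score per patient", {
  ch <- strong_cohort(seed = 13, n = 40, G = 30)
  cv <- suppressWarnings(loocv_risk_scores(ch$mutations, ch$os))
  n <- length(ch$os)
  expect_identical(length(cv$scores), n)
  expect_identical(length(cv$per_fold_models), n)
  expect_equal(cv$cutoff, median(cv$scores))
  expect_identical(as.logical(cv$risk_group == "high"), cv$scores > cv$cutoff)
  # median split: neither side can exceed half the cohort
  expect_lte(sum(cv$scores > cv$cutoff), n / 2)
  expect_lte(sum(cv$scores < cv$cutoff), n / 2)
  expect_true(all(cv$selection_frequency <= n))

  # leakage audit: replacing patient i's outcome must not change fold i
  for (i in c(1L, 7L, 25L, 40L)) {
    oc2 <- ch$os
    oc2$time[i] <- 0.01
    oc2$event[i] <- 1L
    cv2 <- suppressWarnings(loocv_risk_scores(ch$mutations, oc2))
    expect_identical(cv2$per_fold_models[[i]]$genes, cv$per_fold_models[[i]]$genes)
    expect_identical(cv2$per_fold_models[[i]]$mean, cv$per_fold_models[[i]]$mean)
    expect_identical(cv2$per_fold_models[[i]]$sd, cv$per_fold_models[[i]]$sd)
    expect_identical(cv2$per_fold_models[[i]]$coef, cv$per_fold_models[[i]]$coef)
    expect_identical(cv2$scores[i], cv$scores[i])
  }
})

test_that("a strong signal yields significant separation in the right direction", {
  ch <- strong_cohort(seed = 5)
  cv <- suppressWarnings(loocv_risk_scores(ch$mutations, ch$os))
  expect_lt(cv$cv_logrank$p_value, 0.01)
  m_low <- km_estimate(cv$outcome[cv$risk_group == "low"])$median
  m_high <- km_estimate(cv$outcome[cv$risk_group == "high"])$median
  expect_gt(m_low, m_high)
  # the causal genes dominate the selection frequencies
  top <- selection_frequency_report(cv)
  expect_true(all(ch$truth$gene %in% top$gene))
})

test_that("folds with no selected genes keep a zero score", {
  ch <- generate_cohort(sim_config(n_patients = 40, n_genes = 10,
                                   causal_genes = 0, seed = 23))
  cv <- suppressWarnings(loocv_risk_scores(ch$mutations, ch$os, alpha = 1e-6))
  expect_identical(cv$n_empty_folds, 40L)
  expect_true(all(cv$scores == 0))
  expect_null(cv$cv_logrank)  # degenerate grouping, warned
})

test_that("the combined model forces four clinical terms into every fold", {
  ch <- generate_cohort(sim_config(n_patients = 120, n_genes = 40,
                                   causal_genes = 5, causal_log_hr = 1,
                                   clinical_missing_rate = 0, seed = 17))
  ch$clinical$age_gt60[3] <- NA  # one incomplete patient
  cv <- suppressWarnings(suppressMessages(
    loocv_risk_scores(ch$mutations, ch$os, clinical = ch$clinical)))
  expect_true(cv$combined)
  expect_identical(length(cv$scores), 119L)
  for (f in cv$per_fold_models[c(1, 50, 119)]) {
    expect_identical(names(f$coef_clinical),
                     c("age_gt60", "grade3", "stage4", "macroscopic"))
    expect_identical(length(f$coef), length(f$genes))
  }
  expect_message(
    suppressWarnings(loocv_risk_scores(ch$mutations, ch$os,
                                       clinical = ch$clinical)),
    "excluding 1 patient")
})

test_that("the final full-data model reports genes, p-values and coefficients", {
  ch <- strong_cohort(seed = 5, n = 200, G = 60)
  fm <- fit_final_model(ch$mutations, ch$os)
  expect_named(fm$gene_table, c("gene", "p_value", "coefficient"))
  expect_identical(fm$genes, fm$gene_table$gene)
  expect_true(all(fm$sds > 0))
  # coefficients agree with a direct standardized Cox fit
  Xs <- scale(ch$mutations[, fm$genes, drop = FALSE])
  ref <- cox_fit(Xs, ch$os)
  expect_equal(unname(fm$coefficients), unname(ref$coefficients),
               tolerance = 1e-10)
  # scoring is the standardized linear predictor
  expect_equal(predict(fm, ch$mutations),
               as.numeric(Xs %*% fm$coefficients), tolerance = 1e-10)
  expect_warning(fit_final_model(ch$mutations, ch$os, alpha = 1e-12),
                 "no genes selected")
})

test_that("a protective gene gets a negative coefficient", {
  ch <- generate_cohort(sim_config(n_patients = 300, n_genes = 30,
                                   causal_genes = 1, causal_log_hr = -1.2,
                                   mutation_freq_range = c(0.15, 0.3),
                                   seed = 29))
  fm <- fit_final_model(ch$mutations, ch$os)
  expect_true(ch$truth$gene %in% fm$genes)
  expect_lt(fm$coefficients[[ch$truth$gene]], 0)
})

test_that("selection frequencies count folds, descending, omitting never-selected genes", {
  ch <- strong_cohort(seed = 5, n = 150, G = 40)
  cv <- suppressWarnings(loocv_risk_scores(ch$mutations, ch$os))
  rep_tab <- selection_frequency_report(cv)
  expect_false(is.unsorted(rev(rep_tab$folds_selected)))
  expect_true(all(rep_tab$folds_selected >= 1))
  expect_true(all(rep_tab$folds_selected <= length(cv$scores)))
  never <- setdiff(colnames(ch$mutations), rep_tab$gene)
  expect_true(length(never) > 0)  # some genes are never selected
  # a dominant gene is selected in (nearly) every fold
  expect_gte(max(rep_tab$folds_selected), length(cv$scores) - 2L)
})
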