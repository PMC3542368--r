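test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  # no censoring: empirical survival, median = second of three times
  km <- km_estimate(surv_outcome(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  # censored observation reduces later risk sets
  km2 <- km_estimate(surv_outcome(c(1, 2, 3, 4), c(1, 0, 1, 1)))
  expect_equal(km2$event_times, c(1, 3, 4))
  expect_equal(km2$survival, c(3 / 4, 3 / 8, 0))
  # a single censored patient: flat curve, median undefined
  km3 <- km_estimate(surv_outcome(5, 0))
  expect_identical(length(km3$event_times), 0L)
  expect_true(is.na(km3$median))
})

test_that("Kaplan-Meier equals the empirical survivor function without censoring", {
  set.seed(21)
  for (r in 1:10) {
    time <- rexp(sample(5:40, 1), 0.1)
    km <- km_estimate(surv_outcome(time, rep(1, length(time))))
    emp <- vapply(km$event_times, function(t) mean(time > t), numeric(1))
    expect_equal(km$survival, emp, tolerance = 1e-12)
  }
})

test_that("survival, Greenwood variance and median CI match the reference implementation", {
  set.seed(31)
  for (r in 1:20) {
    oc <- random_cohort(sample(15:60, 1))
    km <- km_estimate(oc)
    sf <- survival::survfit(survival::Surv(oc$time, oc$event) ~ 1,
                            conf.type = "log-log")
    sm <- summary(sf, times = km$event_times)
    expect_equal(km$survival, sm$surv, tolerance = 1e-9)
    pos <- sm$surv > 0
    expect_equal(km$greenwood_var[pos], sm$std.err[pos]^2, tolerance = 1e-9)
    qt <- stats::quantile(sf, probs = 0.5)
    # identical convention except when the curve sits exactly at 0.5, where
    # the reference averages the two crossing times
    if (all(abs(km$survival - 0.5) > 1e-9)) {
      expect_equal(unname(km$median), unname(qt$quantile), tolerance = 1e-9)
    }
    ci <- c(qt$lower, qt$upper)
    expect_identical(is.na(unname(km$median_ci)), is.na(unname(ci)))
    ok <- !is.na(ci)
    expect_equal(unname(km$median_ci)[ok], unname(ci)[ok], tolerance = 1e-9)
  }
})

test_that("log-rank statistic is zero for identical groups and matches hand computation", {
  oc <- surv_outcome(c(1, 1, 5, 5, 9, 9), c(1, 1, 0, 0, 1, 1))
  lr <- logrank_test(oc, c(1, 0, 1, 0, 1, 0))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)

  # group A = times (1, 3) both events; group B = (2 event, 4 censored)
  time <- c(1, 3, 2, 4); event <- c(1, 1, 1, 0); grp <- c(1, 1, 0, 0)
  lr2 <- logrank_test(surv_outcome(time, event), grp)
  hand <- hand_logrank(time, event, grp)
  expect_equal(lr2$statistic, hand$statistic, tolerance = 1e-12)
  expect_equal(unname(lr2$observed_minus_expected["group1"]), hand$oe,
               tolerance = 1e-12)

  # label swap leaves the statistic unchanged
  lr3 <- logrank_test(surv_outcome(time, event), 1L - grp)
  expect_equal(lr3$statistic, lr2$statistic, tolerance = 1e-12)
})

test_that("log-rank matches the reference implementation on random cohorts", {
  set.seed(41)
  for (r in 1:50) {
    oc <- random_cohort(sample(10:60, 1))
    g <- random_group(length(oc))
    lr <- logrank_test(oc, g)
    sd <- survival::survdiff(survival::Surv(oc$time, oc$event) ~ g)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-6)
  }
})

test_that("Cox solver reproduces the analytic three-patient solution", {
  oc <- surv_outcome(c(1, 2, 3), c(1, 1, 1))
  fit <- cox_fit(cbind(x = c(1, 0, 1)), oc, ties = "breslow")
  expect_equal(unname(fit$coefficients), -0.5 * log(2), tolerance = 1e-8)
  expect_true(fit$converged)
  # independent grid-search maximization of the partial likelihood
  grid <- seq(-2, 2, by = 1e-4)
  ll <- vapply(grid, grid_cox_loglik, numeric(1),
               x = c(1, 0, 1), time = c(1, 2, 3), event = c(1, 1, 1))
  expect_equal(unname(fit$coefficients), grid[which.max(ll)], tolerance = 1e-3)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("Cox coefficient is zero for two identical outcome groups", {
  time <- rep(c(2, 4, 7, 9), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  x <- rep(c(0, 1), each = 4)
  fit <- cox_fit(cbind(x = x), surv_outcome(time, event))
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)
})

test_that("Cox fits match the reference implementation on random cohorts", {
  set.seed(51)
  for (r in 1:50) {
    n <- sample(20:80, 1)
    oc <- random_cohort(n)
    x <- cbind(a = rnorm(n), b = random_group(n), c = runif(n))
    for (tie in c("efron", "breslow")) {
      fit <- cox_fit(x, oc, ties = tie)
      ref <- suppressWarnings(
        survival::coxph(survival::Surv(oc$time, oc$event) ~ x, ties = tie,
                        control = suppressWarnings(
                          survival::coxph.control(eps = 1e-12, iter.max = 50))))
      expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(unname(fit$standard_errors),
                   unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
      expect_gte(fit$loglik, fit$loglik_null)
    }
  }
})

test_that("Cox partial likelihood at the optimum beats a grid search on tiny instances", {
  set.seed(61)
  for (r in 1:10) {
    n <- 4
    time <- sort(rexp(n, 0.2))
    event <- c(1, 1, 1, rbinom(1, 1, 0.5))
    x <- random_group(n)
    fit <- cox_fit(cbind(x = as.numeric(x)), surv_outcome(time, event),
                   ties = "breslow")
    # separable data has no finite optimum (monotone likelihood): skip
    if (!fit$converged || abs(fit$coefficients[[1]]) > 3.5) next
    grid <- seq(-4, 4, by = 1e-3)
    ll <- vapply(grid, grid_cox_loglik, numeric(1),
                 x = x, time = time, event = event)
    expect_equal(unname(fit$coefficients), grid[which.max(ll)], tolerance = 1e-2)
  }
})

test_that("Cox errors are informative", {
  oc <- surv_outcome(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_error(cox_fit(cbind(flat = rep(1, 4), x = c(0, 1, 0, 1)), oc), "flat")
  expect_error(cox_fit(cbind(x = c(0, 1, 0, 1)),
                       surv_outcome(1:4, rep(0, 4))), "no events")
})

test_that("linear predictor is the plain dot product", {
  oc <- surv_outcome(c(1, 2, 3, 4), c(1, 1, 1, 0))
  fit <- cox_fit(cbind(x = c(1, 0, 1, 0)), oc)
  X <- cbind(x = c(0.5, -1, 2, 0))
  expect_equal(cox_linear_predictor(fit, X),
               as.numeric(X %*% fit$coefficients))
  fit0 <- fit; fit0$coefficients[] <- 0
  expect_equal(cox_linear_predictor(fit0, X), rep(0, 4))
  # single-gene score is coefficient times standardized value
  fit1 <- fit; fit1$coefficients[] <- 0.201804
  z <- c(-0.3, 0, 1.7)
  expect_equal(cox_linear_predictor(fit1, cbind(x = z)), 0.201804 * z)
  expect_error(cox_linear_predictor(fit, cbind(a = 1:4, b = 1:4)), "columns")
})

test_that("group hazard ratio recovers a known effect and orders its CI", {
  set.seed(71)
  n <- 2000
  g <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.05 * exp(log(0.5) * g))
  hr <- group_hazard_ratio(surv_outcome(time, rep(1, n)), g)
  expect_lt(abs(hr[["hr"]] - 0.5), 0.1)
  expect_lt(hr[["ci_low"]], hr[["hr"]])
  expect_gt(hr[["ci_high"]], hr[["hr"]])
  # identical groups: HR 1 inside the CI
  t2 <- rep(c(1, 3, 5, 8), 2); e2 <- rep(c(1, 1, 1, 0), 2)
  hr2 <- group_hazard_ratio(surv_outcome(t2, e2), rep(c(0, 1), each = 4))
  expect_equal(hr2[["hr"]], 1, tolerance = 1e-6)
  expect_true(hr2[["ci_low"]] < 1 && hr2[["ci_high"]] > 1)
})

test_that("chi-square association test matches the textbook formula and reference", {
  expect_equal(association_test(matrix(10, 2, 2))$statistic, 0)
  expect_equal(association_test(matrix(10, 2, 2))$p_value, 1)
  set.seed(81)
  for (r in 1:20) {
    nr <- sample(2:4, 1); nc <- sample(2:3, 1)
    tab <- matrix(rpois(nr * nc, 20) + 1, nr, nc)
    res <- association_test(tab)
    # brute force: sum((O - E)^2 / E)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
    expect_identical(res$df, (nr - 1L) * (nc - 1L))
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(association_test(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(association_test(matrix(1:3, 3, 1)), "2 x 2")
})
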