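# mutsurv

Cross-validated survival risk models from binary somatic-mutation profiles.

`mutsurv` is for biostatisticians and computational oncologists who want to
ask, honestly, whether a tumour cohort's whole-exome somatic mutation
profile predicts survival. The motivating setting is ovarian high-grade
serous carcinoma with overall survival (OS) and progression-free survival
(PFS) endpoints, but the machinery is generic: any patients × genes 0/1
incidence matrix with right-censored outcomes.

## The method

With far more candidate genes than patients, a signature fitted and
evaluated on the same data is guaranteed to look prognostic. `mutsurv`
implements the *complete* leave-one-out cross-validation (LOOCV) design for
survival risk groups:

- for each held-out patient *i*, on the remaining *n − 1* patients: screen
  every gene with the two-group log-rank test (mutated vs. wild-type, keep
  *p* < α = 0.01), standardize the selected columns by training mean and
  *n − 1* SD, and fit a multivariate Cox model
  λ(t | x) = λ₀(t) exp(βᵀz);
- score patient *i* by the fold's Cox linear predictor of their own
  standardized profile (centered at the fold's training-score median so
  held-out scores share a scale);
- split the *n* cross-validated scores at their median into low-/high-risk
  groups, draw the cross-validated Kaplan–Meier curves, and test the spread
  with a **permutation p-value**: the (time, event) pairs are permuted
  jointly, the *entire* LOOCV is rerun on each of B permuted datasets, and
  p = (1 + #{b : p_b ≤ p_obs}) / (B + 1) — the naive log-rank p on reused
  data is optimistically biased, which is the point of the design;
- measure accuracy with cumulative/dynamic time-dependent ROC curves of the
  cross-validated scores at a landmark time (default t = 36 months), using
  a nearest-neighbour estimator of the bivariate survivor function to
  handle censoring, and compare AUC(t) of the genes-only model against a
  combined model with four clinical covariates (age > 60, grade 3, stage 4,
  macroscopic residual) forced into every fold.

The survival primitives — Kaplan–Meier with Greenwood variance and
log(−log) median CIs, the two-group log-rank test, the Newton–Raphson Cox
solver with Efron/Breslow ties, Pearson chi-square association tests — are
implemented in the package (compiled where it matters) and are
cross-checked against the `survival` package to 1e-6 in the test suite.

A synthetic-cohort generator (`sim_config()` / `generate_cohort()`) draws
cohorts with the structure the analysis assumes — sparse Bernoulli
mutations, exponential proportional-hazards survival over a few causal
genes, independent censoring, categorical clinical covariates — so the full
pipeline is testable end to end without patient data. MAF-dialect mutation
files and clinical TSVs are read with `read_maf()` / `read_clinical()`, and
`filter_rare_genes()` / `align_cohort()` apply the cohort filters (drop
genes mutated in < 5 patients; drop patients missing the endpoint).

## Worked example

```r
library(mutsurv)

cfg <- sim_config(n_patients = 300, n_genes = 200, causal_genes = 5,
                  causal_log_hr = 1, seed = 1)
cohort <- generate_cohort(cfg)
cohort
#> <synthetic_cohort> 300 patients x 200 genes, 5 causal gene(s), OS events 196, PFS events 254

cv <- loocv_risk_scores(cohort$mutations, cohort$os, alpha = 0.01)
cv
#> <cv_result> n = 300 (genes-only model), 177/123 low/high risk, 0 empty fold(s)
#>   cross-validated log-rank: chisq = 32.2, p = 1.39e-08

head(selection_frequency_report(cv), 5)
#>       gene folds_selected
#> 1 GENE0014            300
#> 5 GENE0078            300
#> 6 GENE0100            300
#> 8 GENE0171            300
#> 9 GENE0176            300
```

Four of the five genes selected in every fold are planted causal genes
(`cohort$truth`); GENE0100 is a stable false discovery — exactly why the
naive p above must not be trusted. The permutation test reruns the whole
pipeline on outcome-permuted data:

```r
permutation_pvalue(cohort$mutations, cohort$os, B = 99, seed = 2)
#> <perm_result> observed cross-validated log-rank p = 1.39e-08; permutation p = 0.04 (B = 99, add_one estimator)
```

So the separation survives, at p = 0.04 rather than 1e-8. The groups and
their accuracy:

```r
km_estimate(cv$outcome[cv$risk_group == "low"])
#> <km_curve> n = 177, 104 distinct event times, median = 44.4 (95% CI 32.2-56.7)
km_estimate(cv$outcome[cv$risk_group == "high"])
#> <km_curve> n = 123, 92 distinct event times, median = 15.7 (95% CI 10.4-  22)

group_hazard_ratio(cv$outcome, as.integer(cv$risk_group == "high"))
#>       hr   ci_low  ci_high
#> 2.238155 1.682707 2.976953

roc_at_time(cv$scores, cv$outcome, landmark_t = 36)
#> <roc_result> landmark t = 36 months, NNE estimator, AUC = 0.6268
```

Low-risk patients live a median 44.4 months against 15.7 for high-risk
(hazard ratio 2.24 for high vs. low), and the cross-validated score
discriminates 36-month mortality with AUC 0.63. Association of the risk
groups with clinical factors uses plain Pearson chi-square tables, e.g. for
a published cohort's printed risk-group × surgical-outcome counts:

```r
association_test(rbind(microscopic = c(36, 22), macroscopic = c(99, 118)))
#> <chisq> X-squared = 4.954 on 1 df, p = 0.02604
```

`run_pipeline(run_config(...))` orchestrates all of the above (both model
variants, KM/ROC/AUC-over-time/association tables) and writes a
reproducible CSV/JSON bundle with a manifest.

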