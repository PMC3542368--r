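---
title: "Cross-validated survival risk models from somatic mutation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated survival risk models from somatic mutation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutsurv)
```

## The problem

Whole-exome sequencing of a tumour cohort yields, per patient, a binary
profile: for each gene, whether the tumour carries at least one somatic
mutation. Unlike expression data these predictors are sparse 0/1 indicators,
most of them rare. `mutsurv` builds and honestly validates a survival risk
model from such profiles, with ovarian high-grade serous carcinoma — a
tumour type where surgical outcome and platinum response dominate clinical
prognosis — as the motivating setting. Both endpoints of that setting are
supported: overall survival (OS) and progression-free survival (PFS), each a
right-censored (time, event) pair in months.

The central difficulty is that the number of candidate genes far exceeds the
number of patients, so any model fitted and evaluated on the same data will
look spuriously prognostic. The package therefore implements *complete*
leave-one-out cross-validation (LOOCV): every model-building step — gene
screening included — is redone from scratch inside every fold, and
statistical significance of the resulting risk groups is assessed against a
permutation null rather than a chi-square table.

## The procedure

For a cohort of $n$ patients with binary mutation matrix $X$ and outcome
$(T_i, \delta_i)$:

1. **Cohort filters.** Genes mutated in fewer than `min_mutated_patients`
   (default 5) distinct patients are removed; patients missing the chosen
   endpoint are dropped. "Frequency" here counts distinct mutated patients,
   not raw mutation rows, because the incidence matrix is binary.
2. **Per-fold screening.** Leaving out patient $i$, each gene is tested
   mutated-vs-wild-type with the two-group log-rank test; genes with
   $p < \alpha$ (default $\alpha = 0.01$) enter the fold's model.
3. **Per-fold standardization and fit.** Selected gene columns are centered
   and scaled by their training mean and $n-1$ standard deviation; a
   multivariate Cox proportional-hazards model is fitted to the standardized
   columns (Newton–Raphson on the partial likelihood, Efron tie correction
   by default).
4. **Held-out scoring.** Patient $i$'s risk score is the Cox linear
   predictor of their own standardized profile under the fold's model.
5. **Median split and cross-validated curves.** The $n$ held-out scores are
   dichotomized at their median (strictly above = high risk); Kaplan–Meier
   curves and the log-rank statistic comparing the two groups are computed.
6. **Permutation inference.** Because the group labels were derived from the
   same survival data, the naive log-rank p-value is optimistically biased.
   The package permutes the (time, event) pairs jointly across patients,
   reruns the *entire* LOOCV (re-selection included) on each of $B$ permuted
   datasets, and reports $p = (1 + \#\{b: p_b \le p_{obs}\})/(B + 1)$.
7. **Predictive accuracy.** Cumulative/dynamic time-dependent ROC curves of
   the cross-validated scores at a landmark time (default 36 months), using
   a nearest-neighbour estimator of the bivariate survivor function of
   (marker, time) to handle censoring; AUC by trapezoid. `auc_over_time()`
   traces AUC across horizons to compare the genes-only model with a
   combined model that forces four clinical indicators (age > 60, grade 3,
   stage 4, macroscopic residual) unstandardized into every fold. Platinum
   response is never a model covariate — it is unknown at the time the model
   would be applied — and appears only in the association tables.

## Why held-out scores are centered within their fold

Raw out-of-fold linear predictors are not mutually comparable. Every patient
carrying none of a fold's selected genes receives the same fold-specific
constant $-\sum_g \hat\beta_g m_g / s_g$, and that constant depends on the
excluded patient: removing a long-surviving wild-type patient weakens the
apparent mutation effect and *raises* the wild-type score. Within the large
wild-type mass the only score variation is therefore this jitter, which is
almost perfectly rank-correlated with the held-out patient's own outcome. A
median split of the raw pooled scores can then be driven — even inverted —
by an artifact rather than by the signature. `mutsurv` places all held-out
scores on a common scale by subtracting, from each, the median of the
training-set scores under that same fold's model (the prospective-assignment
convention of cross-validated survival risk classifiers); the pooled median
split is then taken on these centered scores. The uncentered predictors are
retained as `scores_raw`.

A residual artifact remains and is worth knowing about: a borderline gene
tends to be selected precisely in the folds that exclude patients who weaken
it, which couples selection flips to the held-out outcome. This is inherent
to complete LOOCV with embedded selection; it is one of the reasons the
permutation null — which reproduces the artifact under the null — is the
only p-value the package advertises for the cross-validated curves.

## The synthetic cohort generator

`sim_config()`/`generate_cohort()` draw cohorts with the structure the
analysis assumes, so the full pipeline is testable without patient data:

* per-gene mutation probabilities uniform on `mutation_freq_range`
  (default 0.02–0.15: the low end sits just above a rare-gene filter of
  5 of 300 patients, the high end reflects the most recurrently mutated
  genes outside outliers), mutations independent across genes and patients;
* survival times exponential with hazard
  $\lambda_0 \exp(\sum_g \beta_g X_{ig})$ over `causal_genes` causal genes
  (default 5 genes at log hazard ratio 1.0); the exponential baseline is
  chosen for closed-form checks (null mean $1/\lambda_0$);
* independent exponential censoring truncated at `max_followup`. Defaults
  (`baseline_hazard` 1/60 per month, `censor_rate` 1/90, `max_followup` 120
  months) give a median OS near 42 months and roughly 55–60% observed
  events — the censoring proportion of the motivating cohort is not
  published, so this sits deliberately inside the 40–60% band a mature
  ovarian-carcinoma cohort would show, and is documented as an assumption;
* PFS is generated as an independent draw with the baseline time scale
  shrunk by `pfs_time_scale` (default 0.4, median near 17 months); the two
  endpoints are modelled as separate problems, as the analysis treats them;
* clinical covariates are drawn categorically with frequencies typical of
  advanced serous carcinoma (grade 3 ~91%, stage 3 ~78%, macroscopic
  residual ~79%, platinum resistance ~35%), independent of the genes by
  default; `residual_confounding` optionally links residual status to the
  genetic risk score. Missingness is MCAR at `clinical_missing_rate`
  (default 3%) per covariate, mimicking the varying denominators of real
  clinical tables.

What the generator does **not** emulate: mutational signatures,
hypermutators, gene–gene correlation, non-proportional hazards, informative
censoring, or outcome-linked clinical covariates (unless the confounding
knob is turned). Tests passing on these cohorts therefore certify the
machinery — leakage-freedom, calibration of the permutation null,
direction-correct recovery of planted signals — not performance on real
tumours.

## Numerical and statistical choices

* **Cox ties**: Efron by default (more accurate under ties); Breslow
  available, and used where an analytic solution is compared (a 3-patient
  instance solves to $\hat\beta = -\tfrac12\ln 2$). Convergence: max
  absolute score $\le 10^{-9}$ or relative log-likelihood change
  $\le 10^{-12}$, step-halving on decrease, at most 50 iterations; monotone
  likelihood is flagged, never an error. Coefficients agree with the
  `survival` package to $10^{-6}$ on random cohorts.
* **Kaplan–Meier**: Greenwood variance; censored observations tied with
  events count as at risk at that time. Median = smallest $t$ with
  $\hat S(t) \le 0.5$ (with a $\sqrt{\varepsilon}$ crossing tolerance);
  where the curve sits exactly at 0.5 over an interval, reference
  implementations that average the two crossing times will differ — a
  documented convention difference. The 95% CI for the median inverts the
  log(−log)-transformed Greenwood band, the convention of the major
  commercial survival packages; the band is undefined where $\hat S$ is 0
  or 1.
* **Chi-square association tests** are Pearson without continuity
  correction, which reproduces the published cohort's printed association
  p-values exactly from the printed counts (e.g. 0.026 for OS risk group ×
  surgical outcome).
* **Screening small-sample behaviour**: for genes with very few mutated
  patients the chi-square reference of the log-rank test is mildly
  anti-conservative; at $n = 300$ and $\alpha = 0.01$ the null selection
  rate is ~1.3% rather than 1.0%. The screen is a ranking device inside the
  cross-validated loop, so this inflation is absorbed by the permutation
  null.
* **Median split ties** go to low risk (high risk means *strictly* above
  the cutoff); with many tied centered scores the two groups may then be
  unequal. If all $n$ scores tie, the grouping is degenerate: the
  cross-validated log-rank is reported as missing with a warning, and such
  permuted datasets contribute $p_b = 1$.
* **Permutation estimator**: add-one, $(1 + \text{hits})/(B + 1)$, so the
  p-value is never exactly zero; ties $p_b = p_{obs}$ count as hits
  (conservative); a plain $\text{hits}/B$ estimator is available. $B = 1000$
  is recommended for confirmatory runs; 100 is a practical exploration
  default.
* **Time-dependent ROC**: cumulative cases (event by $t$) and dynamic
  controls (event-free past $t$). The nearest-neighbour estimator uses a
  symmetric rank-based kernel containing the $2\lambda n$ nearest marker
  percentiles, with `span = "auto"` giving $\lambda = 0.25\,n^{-0.2}$ (the
  reference implementation's convention); rank-based neighbourhoods make
  the AUC exactly invariant under monotone score transformations. A
  subgroup Kaplan–Meier weighting (`estimator = "km"`) is also provided; in
  the uncensored limit it coincides exactly with the empirical binary ROC
  of the event indicator, as does NNE as the span shrinks below the rank
  resolution. Sensitivities/specificities are clipped to [0, 1] and the
  curve made monotone; AUC is trapezoidal over the empirical thresholds
  with (0,0)/(1,1) anchors. ROC is computed on the continuous centered
  scores, never on the dichotomized groups.
* **Combined model**: the four clinical indicators enter unstandardized
  (they are already 0/1 contrasts); patients missing any of the four are
  excluded complete-case, with a message. A fold whose gene selection is
  empty falls back to the clinical-only fit in the combined model, and to a
  zero score in the genes-only model, so all $n$ patients keep a score.
* **Step-1 wording of the procedure** this package follows describes the
  single sample as the "training set"; it is treated as a typo for standard
  LOOCV (train on $n-1$, score the held-out patient), the only reading
  consistent with a complete cross-validation.

## Problem sizes used by the test suite

The suite validates calibration and recovery at desk scale, the package's
own choice of sizes: null calibration with $n = 150$ patients, 200 genes,
$B = 99$ permutations over 50 seeds (permutation p uniform by
Kolmogorov–Smirnov; landmark AUC 0.5 ± 0.05); signal recovery with
$n = 300$, 100 genes, five causal genes at log hazard ratio 1 over 20
replicates (direction-correct group medians and landmark AUC above 0.65).
Power of the *permutation* p-value at that signal strength is partial —
roughly three of five replicates reach $p \le 0.05$ — reflecting the heavy
tail of the cross-validated log-rank statistic's null distribution (stable
spurious selections survive LOOCV in permuted data); the naive
cross-validated log-rank p is below 0.05 in essentially all replicates, and
detection improves with stronger or more frequent causal mutations.

## Known limitations

* No v-fold or bootstrap resampling, no penalized Cox, no stratified
  log-rank, no time-varying covariates, no incident/dynamic ROC and no
  IPCW estimator, no AUC confidence bands.
* The rare-gene filter is applied to the full matrix before
  endpoint-specific patient exclusion by default; filtering after exclusion
  is a one-line variant the reader can apply by reordering the calls.
* LOOCV at these scales is compute-intensive by construction: a permutation
  run executes the complete pipeline $B + 1$ times. The screening and Cox
  layers are compiled for this reason.
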