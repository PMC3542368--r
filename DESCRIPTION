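Package: mutsurv
Title: Cross-Validated Survival Risk Models from Somatic Mutation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates survival risk models from binary somatic
    mutation profiles. Implements complete leave-one-out cross-validation with
    per-fold log-rank gene screening, standardized multivariate Cox risk
    scores, median dichotomization into low- and high-risk groups,
    cross-validated Kaplan-Meier curves with a permutation null for the
    cross-validated log-rank statistic, and cumulative/dynamic time-dependent
    ROC curves at a landmark time using a nearest-neighbour bivariate survival
    estimator. Includes a Mutation Annotation Format (MAF) dialect reader,
    cohort filters for rare genes and missing outcomes, and a synthetic-cohort
    generator for testing the full pipeline without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
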