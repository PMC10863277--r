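Package: methylscreen
Title: Age- and Sex-Adjusted Methylation Outlier Detection and
    Imprinting-Disorder Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects per-probe DNA methylation outliers from array beta
    values using age- and sex-adjusted reference ranges. Per-probe
    location-scale models (Gaussian on the logit scale, penalized spline
    age smooths, additive sex shifts) are fitted to a control cohort and
    discretized onto a fine age-by-sex grid; samples are scored with
    unadjusted, adjusted, and regularized z-scores. Includes a
    simulation framework for type-I error and statistical power of the
    three detection variants across cohort sizes, a synthetic-cohort
    generator with probe-level age trends, sex offsets and
    disorder-specific regional or diffuse methylation effects, and a
    downstream classification pipeline: stratified splitting, z-score
    probe filtering, target-probe plus UMAP global features,
    correlation pruning, a bagged weighted ensemble of heterogeneous
    base learners, and evaluation with exact binomial confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    FNN,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
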