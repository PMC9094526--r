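Package: divprop
Title: Propensity-Score Diversity Analysis for Multi-Site Predictive Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cohort diversity in multi-site case-control studies with
    propensity scores and measures its effect on out-of-distribution predictive
    accuracy and on the stability of extracted predictive patterns. Provides
    covariate-only propensity estimation with Platt calibration,
    caliper-constrained optimal pair matching with balance diagnostics,
    score-ordered stratification, contiguous/diverse/random train-holdout
    sampling schemes with within- and out-of-distribution diversity indices,
    nested cross-validated L2-penalized logistic classification of parcel-level
    brain features, linear and empirical-Bayes location-scale (ComBat-style)
    deconfounding, coefficient-stability analysis with permutation
    threshold-free cluster enhancement, and a seeded synthetic multi-site
    cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva,
    glmnet,
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
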