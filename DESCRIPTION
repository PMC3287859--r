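Package: snplasso
Title: Two-Stage LASSO SNP Selection with Stepwise Refinement and
    Bootstrap Stability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model selection for quantitative-trait genome-wide association
    data by simultaneous analysis of all common SNPs.  Implements a
    Gaussian-response LASSO with unpenalized covariates solved by cyclical
    coordinate descent over a warm-started penalty path, 10-fold
    cross-validation with the lambda.min and one-standard-error rules and
    repeated-CV median aggregation, bidirectional stepwise AIC/BIC
    refinement of the LASSO candidate set, and bootstrap bagging of the
    LASSO stage yielding resample model inclusion proportions (RMIP).
    Includes a synthetic-data generator emulating an exome-style panel of
    unrelated individuals with additive common-variant effects on a
    quantitative trait, so every stage of the pipeline can be exercised and
    scored against a known simulating model.  All user-facing functions
    return tibbles; fitted objects have tidy(), glance() and autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
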