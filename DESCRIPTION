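Package: clustercal
Title: Flexible Calibration Curves for Risk Predictions in Clustered Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses the calibration of binary-outcome risk predictions in
    clustered (multicenter or multi-study) data. Provides three estimators of
    the average-cluster flexible calibration curve with confidence and
    prediction intervals: clustered group calibration via bivariate random
    effects meta-analysis (CG-C), two-stage pointwise univariate random
    effects meta-analysis of cluster-specific smoothers (2MA-C, restricted
    cubic splines or LOESS), and a one-stage logistic mixed model with spline
    random effects (MIX-C). Includes a clustered simulation engine (random
    intercept logistic data-generating models calibrated to target ICC, AUC
    and event rate), mean squared calibration error and prediction interval
    coverage metrics, and ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    metafor,
    lme4,
    MASS,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
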