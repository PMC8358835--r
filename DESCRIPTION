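Package: scsga
Title: Sparse Granger Causality Analysis of Multichannel EEG with
    Sensor-Correlation Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of directed (effective) connectivity between
    multichannel time-series sensors via sparse multivariate
    autoregression. Implements four Granger-causality estimators: the
    classical L2 (least-squares) fit, LASSO (L1-penalized least squares),
    LAPPS (L1 fitting loss with an L1/2 penalty, solved by ADMM with
    half-thresholding), and a sensor-correlation weighted variant (SC-SGA)
    that scales predictor channels by their Pearson correlation with the
    target channel. Includes frequency-band decomposition of recordings,
    directed-network feature extraction, an evaluation harness (regularized
    logistic regression, ridge classifier, stratified repeated
    cross-validation, confusion-matrix metrics), and a generator of stable
    sparse VAR data with optional outlier contamination for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
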