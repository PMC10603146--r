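Package: survsel
Title: Variable Selection for High-Dimensional Censored Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Benchmarked variable-selection toolkit for right-censored
    survival data with many, highly collinear covariates. Implements
    penalized Cox models (lasso, elastic net, ridge, adaptive lasso) with
    10-fold cross-validated grid search, posterior-mode spike-and-slab
    Bayesian Cox models (Gaussian-mixture SSVS, double-exponential
    spike-and-slab lasso, and its group-structured extension), a random
    survival forest with minimal-depth selection, and thresholding rules
    that turn continuous posterior estimates into selected sets
    (confidence-interval rule, BIC thresholding, and a greedy modified BIC
    thresholding). A simulation module generates survival data with
    block-autoregressive collinearity, sparse protective effects,
    exponential event times, and censoring calibrated to a target rate,
    and a benchmark harness scores every method x rule combination by
    true-positive, true-negative, and false-positive rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
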