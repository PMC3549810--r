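Package: fealect
Title: Feature Relevance Scoring and Selection from the Lasso Regularization Path
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the relevance of features in high-dimensional (n << d)
    classification and regression problems by repeatedly subsampling the
    training data, recovering the full least-angle-regression (LARS) entry
    order of each subsample, and crediting each feature with the harmonic
    1/k weight of every path size at which it is active.  Informative
    features are separated from irrelevant ones by fitting a continuous
    quadratic-linear-quadratic three-segment model to the sorted log-score
    curve: features above the linear (irrelevant) segment are selected,
    without any user-chosen threshold.  Includes Bolasso and Bolasso-S
    baseline selectors, held-out AUC comparison of selectors, exact
    subset-inclusion combinatorics for subsampling without replacement, a
    mock-path harness validating the exponential score law for
    over-fitting features, and a seeded sparse linear-model simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
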