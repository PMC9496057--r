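Package: pcrcall
Title: Amplification-Curve Classification and Ct Calling for Point-of-Care qPCR
Version: 0.1.0
Authors@R:
    person("pcrcall", "developers", email = "pcrcall@example.org", role = c("aut", "cre"))
Description: Analysis core for a point-of-care qPCR platform: seeded simulation
    of six amplification-curve morphology classes, per-feature normalization and
    principal-component projection, a five-classifier comparison harness
    (support vector classifier with an in-package SMO solver, ridge multinomial
    logistic regression, k-nearest neighbours, CART decision tree, linear
    discriminant analysis) with stratified 7:3 splitting and 5-fold grid-search
    cross-validation, five-parameter logistic fitting of positive curves by
    damped Gauss-Newton iteration with Ct reported as the second-derivative
    maximum, abnormal-cause inference, risk-level binning, Pearson method
    agreement validation, and JSON/HTML run reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
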