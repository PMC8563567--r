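Package: dfcstates
Title: Dynamic Functional Connectivity States from Network Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Static and dynamic resting-state functional-connectivity
    analysis for per-subject network time-course matrices. Implements
    tapered sliding-window connectivity with graphical-LASSO precision
    estimation and cross-validated regularisation, Fisher r-to-z
    transformation, connectivity-variability metrics, k-means brain-state
    clustering with Manhattan distance and elbow-based model selection,
    the window-free leading-eigenvector (LEiDA) phase-coherence pathway
    with functional-connectivity-dynamics matrices, between-network static
    full/partial correlations with max-statistic permutation inference,
    and nonparametric group statistics. Includes a Markov-switching
    multivariate Gaussian cohort simulator with planted connectivity
    states for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
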