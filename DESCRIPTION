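Package: sonarCEE
Title: Behavioural Response Analysis for Whale Sonar Controlled Exposure
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing behavioural responses of baleen whales to
    controlled exposure experiments (CEEs) with mid-frequency active sonar
    and pseudorandom noise. Provides a synthetic-data generator for CEE
    ping schedules, received-level fields and per-dive behaviour; dive
    segmentation and behavioural-metric extraction from tag series; a
    multivariate hidden Markov model with discrete random-effect contexts
    and received-level covariates on state transitions; PCA-based
    group-level response models with penalized-spline smooths; Mahalanobis
    change metrics; and dose-as-time exposure-response survival analysis
    of expert severity scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    survival,
    mgcv,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
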