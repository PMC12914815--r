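Package: mlbridge
Title: Multilayer Partial-Correlation Networks and Bridge Centrality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of regularized partial-correlation networks (Gaussian
    graphical models with graphical-LASSO penalisation and EBIC model
    selection) over multilayer cohort data in which nodes belong to declared
    layers such as mental health, cognition and regional gray-matter volume.
    Provides covariate residualization, mixed ordinal/continuous correlation
    estimation, bridge-strength centrality with percentile-based bridge-node
    designation, case-dropping bootstrap stability (CS coefficient), a
    synthetic multilayer-cohort generator for testing and power exploration,
    and an end-to-end configured pipeline with delimited-text, GraphML and
    JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
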