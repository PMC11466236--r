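Package: clpnet
Title: Cross-Lagged Panel Network Analysis of Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of cross-lagged panel networks (CLPN)
    for two-wave ordinal symptom data, aimed at comorbidity research on
    non-suicidal self-injury (NSSI), depression and anxiety. Each wave-2
    symptom is regressed on all wave-1 symptoms plus covariates with an
    L1 (lasso) penalty tuned by K-fold cross-validation; the fitted directed
    network supports expected-influence centrality, bridge-edge ranking,
    display thresholding, non-parametric bootstrap confidence intervals for
    edge weights, and similarity indices (edge correlation, overlap,
    Jaccard) between group-specific networks. A latent-normal threshold
    simulator generates two-wave panels from known group-specific networks
    so the whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
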