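Package: strokesim
Title: Generative Whole-Brain Hopf Models for Predicting Stroke Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a whole-brain network model of coupled Stuart-Landau (Hopf)
    oscillators to a healthy cohort by estimating generative effective
    connectivity (GEC) with a greedy gradient-descent update on functional
    connectivity and time-shifted covariance targets, then "lesions" the
    fitted model with patient-specific structural-disconnection masks to
    generate simulated BOLD and functional connectivity for stroke patients
    without refitting. Includes a fully seeded synthetic-cohort generator,
    functional-connectivity stroke signatures (intra-hemispheric DAN-DMN
    coupling, homotopic inter-hemispheric connectivity, Newman modularity),
    graph metrics (global efficiency, FC entropy, average degree), z-scored
    FC abnormality matrices, cross-validated partial least-squares behaviour
    prediction, and an end-to-end study pipeline with model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    igraph,
    mixOmics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
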