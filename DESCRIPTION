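Package: painnet
Title: Regularized Partial-Correlation Networks for Mixed Questionnaire Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation and stability analysis of regularized partial-correlation
    (Gaussian graphical model) networks over mixed continuous/binary
    patient-reported outcome data, as used in symptom-network studies of
    post-COVID pain. Provides a synthetic-cohort generator driven by a planted
    partial-correlation network, complete-case filtering, Pearson/polyserial
    mixed correlation matrices with positive-definite repair, graphical lasso
    with EBIC model selection (compiled blockwise coordinate descent),
    strength/closeness/betweenness centrality with min-max scaling,
    nonparametric edge-weight bootstraps, case-dropping subset bootstraps and
    the correlation-stability (CS) coefficient, and a single orchestrated
    pipeline with reproducible seeding and file exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    MASS,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
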