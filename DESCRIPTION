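Package: fcnull
Title: Group-Average Null Models for Individual-Level Functional Connectome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Benchmarking framework for individual-level prediction of functional
    connectivity (FC) from structural connectivity (SC) in parcellated human
    connectome data. Implements the group-average (avgFC) and noisy group-average
    (navgFC) null predictors together with the evaluation statistics used to judge
    individual-level structure-function models: per-subject prediction correlations
    under 10-fold cross-validation, concatenated variance explained, preservation of
    inter-individual differences, per-parcel and Yeo-7 network error maps, graph
    centrality reproduction on significance-thresholded FC, and lasso-based
    cognition-prediction controls with structural connectivity regressed out.
    Includes a calibrated synthetic connectome cohort generator (coupled FC, SC and
    cognition with controllable inter-subject similarity) so every analysis stage is
    testable without access-controlled neuroimaging data, rank-based Gaussian
    resampling of streamline-count matrices, and a minimal feed-forward network
    predictor with a variance-preserving loss for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    glmnet,
    igraph,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
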