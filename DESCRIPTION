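Package: cadnet
Title: Genetic-Algorithm-Tuned Elastic Net Classification of Obstructive
    Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Development and blinded verification of a linear classifier for
    obstructive coronary artery disease from high-dimensional resting-signal
    features. Implements a worst-case-lesion modified Gensini score as the
    continuous training target, a weighted elastic net fitted by cyclic
    coordinate descent on the unnormalised penalised least-squares loss,
    correlation-based feature reduction, and a genetic algorithm that tunes
    the five pipeline hyperparameters against a noise-subset-weighted AUC
    fitness. Includes a seeded synthetic cohort generator with planted sparse
    signal and block-correlated features, diagnostic performance evaluation
    (sensitivity, specificity, NPV, PPV, AUC) with BCa bootstrap confidence
    intervals, and demographics comparison utilities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    boot
Config/testthat/edition: 3
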