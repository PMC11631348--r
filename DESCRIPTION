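Package: conniq
Title: Interpretable Prediction of Intelligence Components from Multi-State
    Functional Brain Connectivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An interpretability-first pipeline for predicting general,
    crystallized, and fluid intelligence from functional brain connectivity
    measured across multiple cognitive states. Provides a synthetic cohort
    generator with planted ground truth (family structure, confound leakage,
    state-varying signal, redundant relevant edges), bifactor and
    exploratory-factor psychometric scoring, Fisher-z connectivity with
    connection-wise latent factor analysis across states, systematic
    connection-selection schemes (whole-brain, network-based, theory-driven,
    random-edge and random-node nulls, relevance-based top-k), family-aware
    stratified cross-validation with out-of-sample deconfounding, multilayer
    perceptron regression with inner-loop hyperparameter search and early
    stopping, stepwise layer-wise relevance propagation for edge attribution,
    permutation-based performance and model-difference tests, and brain-graph
    characterization of relevant connections (participation coefficient,
    within-module degree z-score, retest ICC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
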