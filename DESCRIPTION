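Package: bcfqsar
Title: Machine Learning QSAR Models for Bioconcentration Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models log-transformed bioconcentration factors (logBCF) of
    organic chemicals in aquatic species from molecular descriptors.
    Provides descriptor-table ingestion, cleaning and splitting; wrapper
    feature selection by a genetic algorithm or stepwise search with a
    generalized regression neural network (GRNN) monitoring the holdout
    error; multilayer-perceptron, radial-basis-function and baseline
    (ordinary least squares, ridge, k-nearest-neighbour) regressors with
    early stopping; a principal-component applicability domain with a
    chi-squared distance threshold; descriptor-importance analysis by
    error ratios; REACH bioaccumulation (nB/B/vB) classification with
    confusion accounting; and a synthetic descriptor/response generator
    with planted collinearity, a saturating hydrophobicity effect and
    descriptor-space outliers so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
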