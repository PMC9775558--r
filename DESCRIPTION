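Package: betapair
Title: Beta-Pairing Propensity Features for Protein Phase-Separation Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans protein sequences for the lowest-energy cross-beta pairings
    between two stretches of the same chain, using orientation-specific 20x20
    residue-pair statistical potentials, and summarises each sequence by its
    best pairing energy, pairing length and average register shift. These
    features are combined linearly with an externally computed pi-pi contact
    score (PScore) into composite liquid-liquid phase-separation predictors
    whose weights are trained by Nelder-Mead maximisation of the training-set
    AUC under repeated k-fold cross-validation. Includes ROC/AUC and Matthews
    correlation evaluation utilities, synthetic sequence and feature
    generators for fully reproducible benchmarking, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
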