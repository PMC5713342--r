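Package: lctdppi
Title: Protein-Protein Interaction Prediction with Local Conjoint Triad
    Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-based prediction of protein-protein interactions.
    Protein sequences are reduced to a seven-letter alphabet grouped by
    side-chain dipole and volume, then encoded with the local conjoint
    triad descriptor (LCTD): composition, transition, distribution and
    conjoint-triad statistics computed on ten overlapping continuous and
    discontinuous sequence regions, concatenated for both partners of a
    pair. Also provides the whole-sequence conjoint triad (CT) and local
    descriptor (LD) baselines, a feed-forward neural network classifier
    with dropout, batch normalization and Adam, confusion-matrix metrics
    with ROC/AUC, stratified k-fold cross-validation, a synthetic
    interaction-dataset generator with localization-aware negative
    sampling, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
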