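Package: cciboost
Title: Sparse Boosting-Autoencoder Analysis of Single-Cell Cell-Cell
    Interaction Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end workflow for dimensionality reduction of
    single-cell-resolved cell-cell interaction data. Builds a cell-cell
    interaction matrix (CCIM) from expression data and a ligand-receptor
    database, fits a boosting autoencoder whose linear encoder is trained
    by componentwise gradient boosting for sparse feature selection, adds
    a split-softmax soft-clustering layer so that clusters of cell pairs
    are learned jointly with ranked sets of characterizing ligand-receptor
    interactions, and exports cluster assignments, ranked interaction
    lists, and 2D embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    rlang,
    yaml,
    uwot,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
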