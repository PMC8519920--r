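Package: duplexr
Title: DNA Hybridisation Yield Prediction and Orthogonal Library Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting the equilibrium hybridisation yield of
    single-stranded DNA pairs and for designing orthogonal sequence
    libraries. Provides a mutation-driven synthetic dataset generator with
    a two-state nearest-neighbour thermodynamic yield oracle (plus an
    optional NUPACK wrapper), semi-global affine-gap alignment and
    thermodynamic feature extraction for classical baseline classifiers,
    one-hot image and token encodings of sequence pairs, convolutional and
    bidirectional-LSTM yield regressors trained by mean squared error,
    classification metrics after yield binarisation, and a scalable
    longest-common-substring candidate-pair filter (exact k-mer join, with
    an optional MMseqs2 backend) feeding batch yield screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    MASS,
    randomForest,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
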