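Package: drugsyn
Title: Multimodal Prediction of Synergistic Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a drug pair acts synergistically or
    antagonistically in a given cancer cell line by fusing two feature views
    of each drug pair-cell line triplet: a one-dimensional view built from
    chemical-language drug vectors and an expression-compressing multilayer
    perceptron over landmark genes, and a two-dimensional view built from
    graph-convolutional molecular graph embeddings and node2vec
    protein-protein interaction embeddings pooled through transformer
    encoder layers with multi-head attention. Includes Loewe-score
    preprocessing and labelling, random and leave-group-out
    cross-validation, an eight-metric evaluation panel, attention-score
    interpretability, and a synthetic-data generator with a planted
    decision rule for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
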