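Package: hmcpred
Title: Hybrid Sequence-Feature Prediction of 5-Hydroxymethylcytosine Sites in RNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts 5-hydroxymethylcytosine (5hmC) modification sites in RNA
    sequences from sequence alone. Seven nucleotide encoding schemes (k-mer
    composition, reverse-complement k-mer composition, pseudo di- and
    tri-nucleotide composition, and di-/tri-nucleotide auto- and
    cross-covariance over physicochemical property profiles) are fused into a
    174-dimensional hybrid feature vector, reduced by principal component
    analysis, and classified with a small feed-forward neural network trained
    by backpropagation with dropout and L2 regularisation. Includes stratified
    K-fold cross-validation with sensitivity, specificity, MCC and ROC/AUC
    reporting, a grid-search tuner for learning rate and activation, a
    synthetic benchmark generator with a planted motif signal, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    randomForest,
    rpart,
    class
Config/testthat/edition: 3
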