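Package: lncgan
Title: LncRNA-Disease Association Prediction with a Bidirectional
    Adversarial Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts unverified lncRNA-disease associations by training a
    bidirectional generative adversarial network (encoder, generator and
    discriminator) on integrated similarity feature vectors. Features combine
    weighted edit-distance sequence similarity between lncRNAs, directed
    acyclic graph based disease semantic similarity, and Gaussian interaction
    profile kernel similarities derived from the binary association matrix.
    Includes a k-fold cross-validation harness with ROC/AUC, precision-recall,
    accuracy, F1 and Matthews correlation metrics, a synthetic benchmark
    generator with planted block structure, file readers and writers for the
    standard input formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
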