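Package: textcam
Title: Explainable Medical-Text Classification with Text-as-Image CNNs and Grad-CAM
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies clinical abstracts by arranging each document's tokens
    in a fixed 25x25 grid, embedding tokens with skip-gram hierarchical-softmax
    word vectors so that embedding dimensions act as image channels, and
    training a channel-adapted residual convolutional network by transfer
    learning. Predictions are explained with gradient-weighted class activation
    mapping (Grad-CAM) projected back onto tokens, rendered as heatmaps and
    highlighted text. Includes a 1-D convolutional and a tf-idf naive Bayes
    baseline, support-weighted multiclass metrics, a seeded synthetic
    keyword-planted corpus generator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
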