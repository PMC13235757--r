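Package: neuralign
Title: Multi-Stage Neural Alignment Co-Training for Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Co-trains a CORnet-Z style convolutional network on image
    classification while aligning its V1-, V4- and IT-corresponding block
    representations with stimulus-response recordings from the primate
    ventral visual stream. Implements three differentiable alignment
    objectives (deep canonical correlation analysis, InfoNCE/NT-Xent and
    VICReg) with analytic gradients, scoped backpropagation of each
    alignment term through the network prefix that feeds it, matched-seed
    experiment management, a shuffled-pairing control, and a corruption
    robustness evaluation protocol based on severity-averaged accuracies,
    relative gains, paired t-tests and Benjamini-Hochberg false discovery
    rate correction. A synthetic-data module generates desk-scale
    classification tasks, teacher-derived neural response sets and
    parametric image corruptions so the whole pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
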