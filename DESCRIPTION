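Package: acnescan
Title: Patch-Based Convolutional Diagnosis of Facial Acne Vulgaris
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage automatic diagnosis of facial acne vulgaris from RGB
    face images. A sliding window tiles a face into 50x50 patches; a binary
    skin/non-skin convolutional classifier masks non-skin tiles and a
    seven-class classifier (papule, cyst, blackhead, normal skin, pustule,
    whitehead, nodule) labels the remaining skin tiles. Per-class tile
    proportions over the skin area are aggregated into an integral report and
    a symptom set. Includes the affine augmentation matrices used to enlarge
    patch data sets, a small self-contained CNN training engine (convolution,
    max-pooling, dropout, dense layers, Adam and SGD optimizers), ROC/AUC and
    Youden-index threshold selection, normalized confusion matrices, and a
    synthetic patch and face generator so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
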