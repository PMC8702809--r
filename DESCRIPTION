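Package: retseg
Title: Retinal Vessel Segmentation with a Residual Attention Encoder-Decoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end retinal vessel segmentation for color fundus photographs.
    Implements the full pipeline: green-channel extraction, Gaussian denoising,
    field-of-view restricted histogram equalization and gamma correction;
    sliding-window 64x64 patch extraction with per-epoch augmentation and
    overlap-averaged stitching; an encoder-decoder convolutional network built
    from residual blocks, atrous spatial pyramid pooling and residual attention
    modules with three deep-supervision heads; class-balanced binary
    cross-entropy with an epoch-scheduled auxiliary-loss weight; Adam training,
    full-image inference, and pixel-level evaluation (accuracy, sensitivity,
    specificity, ROC/AUC) inside the field of view. A synthetic fundus
    generator produces disc-masked images with branching vessel trees and
    paired ground truth so the whole pipeline is testable without downloading
    the DRIVE or STARE benchmarks.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
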