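Package: fracdet
Title: Anchor-Free Fracture Detection with Average-Pooling Downsampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-stage, anchor-free object-detection toolkit for
    radiograph fracture grading (AO/OTA A1-A3). Implements a YOLOv8n-style
    detector in which stride-2 convolutional downsampling sites in the
    backbone and PAN neck can be replaced by ADown blocks (2x2 average
    pooling, channel split, a strided 3x3 convolution branch and a max-pool
    plus 1x1 convolution branch, concatenated). Provides exact per-layer
    parameter and FLOP accounting, the class-weighted detection objective
    (binary cross-entropy classification, CIoU box regression, distribution
    focal loss) with task-aligned target assignment, CPU training via
    hand-written backpropagation over Rcpp tensor primitives, COCO-style
    PR/AP/mAP evaluation with normalized confusion matrices, a YOLO-format
    data pipeline with mosaic/flip/HSV augmentation, and a seeded synthetic
    femur-phantom generator emulating an imbalanced three-class clinical
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
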