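Package: vesselcascade
Title: Bidirectional Multi-Scale Cascade Networks for Retinal Vessel
    Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Retinal vessel segmentation as multi-scale contour detection.
    Implements a bidirectional symmetric cascade network: a VGG16-derived
    backbone split into five scale detection blocks, dense dilated
    convolution modules with exponentially increasing dilation rates, two
    complementary diameter-specific supervision targets per stage built
    from the other stages' predictions, and a class-balanced thresholded
    cross-entropy loss. Ships a synthetic fundus-scene generator with
    per-pixel vessel width annotation so the whole pipeline (patch
    extraction, augmentation, training with a poly learning-rate schedule,
    and pixel-level Se/Sp/Acc/Pr/F1/Dice/ROC-AUC evaluation) is exercisable
    end-to-end on CPU without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
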