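Package: slideqc
Title: Quality Control of Whole-Slide Images by Tissue and Artifact Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-module quality control for H&E whole-slide images: a tissue
    detector working at low magnification gates a multi-class artifact
    segmenter (folds, dark spots and foreign objects, pen markings, air
    bubbles and slide edges, out-of-focus regions) run at 5x, 7x or 10x
    objective magnification. Includes a synthetic-slide simulator with
    pixel-exact ground truth and a synthetic out-of-focus generator, an
    MPP-aware tiling and mask-stitching layer, a trainable compact
    encoder-decoder segmentation network, Dice and confusion-matrix
    evaluation, slide-quality benchmarking statistics (institute ranking,
    paired scanner comparison, temporal monitoring), and artifact masking for
    downstream image-analysis algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
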