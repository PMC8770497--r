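Package: mafcdn
Title: Microaneurysm Segmentation in Fundus Fluorescein Angiography with
    Fully Convolutional DenseNets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects retinal microaneurysms in fundus fluorescein
    angiography (FFA) images by semantic segmentation. Provides grayscale
    image and binary mask types with lossless PNG/TIFF input and output,
    two-stage contrast enhancement (linear histogram stretching followed
    by Gaussian filtering with reflect padding), configurable fully
    convolutional DenseNet segmentation networks (FC-DenseNet56/67/103
    presets and custom variants) trained with a focal or cross-entropy
    pixel loss via a built-in CPU engine, a six-metric pixel-level
    evaluation suite (pixel accuracy, mean pixel accuracy, precision,
    recall, F1, mean intersection over union), a synthetic FFA scene
    generator with paired ground-truth masks, and a training, prediction,
    evaluation and ablation harness with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
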