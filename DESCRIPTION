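Package: proxidet
Title: Pixel-to-Pixel Convolutional Regression for Nucleus Detection in
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects nucleus centers in stained microscopy images by
    fully convolutional regression of proximity maps. Point annotations
    are encoded as exponentially decaying proximity maps, a residual
    encoder-decoder network with concatenation skips and multi-context
    aggregation regresses the map pixel-to-pixel, and nucleus centers are
    recovered as local maxima after relative thresholding. Includes a
    weighted mean-squared-error objective that counteracts the all-zero
    trivial solution, fine-tuning with block freezing, mixed-source
    training with a balance weight between target and auxiliary data,
    Hungarian-assignment evaluation (precision, recall, F1, localization
    distance, precision-recall curves), and a seeded generator of
    H&E-like synthetic images for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
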