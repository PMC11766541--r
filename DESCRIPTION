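Package: standcount
Title: Plant Stand Counting in UAV Orthomosaics by Semantic Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates seedling-stage plant stand counts from UAV RGB field
    imagery. Provides a synthetic row-crop scene simulator with exhaustive
    ground truth, normalization of orthomosaics to a common 1 px = 1 cm grid,
    rasterization of point annotations into disc masks, an encoder-decoder
    (U-Net style, ResNet-family encoder) semantic segmentation network trained
    with a combined Dice and cross-entropy loss, contour- and area-based plant
    counting, tile-wise count agreement metrics (MAE, MAPE, Pearson and
    Spearman correlation, pixel IoU), and gray-level co-occurrence and
    run-length texture profiling of plant masks for cropping-pattern analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    withr,
    png,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
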