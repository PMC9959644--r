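Package: mrfit
Title: Moisture-Ratio Model Estimation for Plant-Tissue Drying by
    Evolutionary Maximum Likelihood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits polynomial models of moisture ratio versus area shrinkage
    for plant-tissue (e.g. cantaloupe slice) drying experiments using two
    differential-evolution estimators whose fitness is the profiled Gaussian
    maximum likelihood: a classic rand/1/bin variant and an improved variant
    with fitness-sorted mutation, an exponentially decaying scaling factor
    and a sinusoidal crossover-rate schedule with a two-generation hold.
    Includes an image-segmentation pipeline that measures slice shrinkage
    from photographs (grayscale conversion, Otsu thresholding, hole filling,
    particle filtering, pixel-area ratios), goodness-of-fit metrics with
    adjusted R-squared model-order selection, a synthetic-data generator for
    drying trajectories and shrinking-disk image stacks, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
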