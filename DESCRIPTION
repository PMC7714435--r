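Package: adipoquant
Title: Adipocyte Morphometry from Calibrated Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies white adipocyte number and size from calibrated
    brightfield histology images (H&E). Implements three segmentation
    front-ends over one particle-analysis core: an edge-based whole-slide
    pipeline (iterated Sobel "find edges" plus binarisation), an
    intensity-threshold whole-slide pipeline (membrane/fat split at the
    230/231 boundary with hole filling), and a micrograph pipeline
    (percentile thresholding with membrane dilation). Detections are
    filtered by area, circularity and perimeter windows, summarised per
    slide, binned into 500 square-micron histograms, and compared across
    diet groups (Kruskal-Wallis with Dunn post-hoc, Student's t) and
    across methods (Bland-Altman limits of agreement, linear regression).
    Includes a seeded synthetic adipose-tissue generator with per-cell
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
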