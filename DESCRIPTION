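Package: pathomics
Title: Pathomics Feature Extraction and Treatment-Response Modeling for H&E Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pathomics pipeline for hematoxylin-and-eosin (H&E)
    histopathology: tiling of RGB slide exports with a tissue-content filter,
    Beer-Lambert optical-density conversion and two-stain spectral
    deconvolution, three-compartment segmentation (tissue-fold removal, Otsu
    nuclei, seeded shortest-path propagation of whole cells, cytoplasm by
    subtraction), multi-family quantitative feature extraction (intensity,
    radial intensity distribution, Haralick texture, Zernike shape, geometry,
    object neighborhoods, granularity, stain colocalization, image quality),
    case-level distributional aggregation, k-nearest-neighbor mutual-information
    feature selection, and nested cross-validated support-vector-machine
    classification of binary treatment response. Includes a seeded synthetic
    H&E cohort generator with ground-truth masks so the whole pipeline is
    testable without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
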