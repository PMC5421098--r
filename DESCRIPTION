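Package: histocode
Title: Two-Level Bag-of-Visual-Words Texture Coding and Classification of
    H&E Histopathology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds image-level surrogate biomarkers from haematoxylin-eosin
    (H&E) stained tissue images. RGB tiles are unmixed into stain intensity
    channels by colour deconvolution, local texture is summarised by a fixed
    Gabor filter bank over 32x32 pixel patches, and images are recoded by a
    two-level bag-of-visual-words scheme: a generic patch-level codebook
    followed by class-specific codebooks over neighbourhood code-frequency
    vectors. The resulting code histograms feed an RBF-kernel support vector
    machine with recursive feature elimination, tuned and evaluated inside a
    nested stratified cross-validation that refits every codebook per fold.
    Evaluation utilities cover confusion-matrix metrics with Agresti-Coull
    intervals, rank-based AUC with bootstrap intervals, chi-squared
    association tests, univariable logistic feature polarity, and spatial
    feature maps. A synthetic pseudo-H&E cohort generator with controllable
    two-scale texture structure makes the whole pipeline testable without
    slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    tiff,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
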