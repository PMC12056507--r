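Package: spheroseg
Title: Segmentation and Morphometric Analysis of Tumor Spheroids in
    Brightfield Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic segmentation of multicellular tumor
    spheroids in brightfield microscopy images, including treated
    spheroids obscured by dead-cell debris.  Provides a seeded synthetic
    image generator with ground-truth masks, a trainable convolutional
    encoder-decoder segmenter with Dice/cross-entropy/focal losses, a
    1-cycle learning-rate policy and validation-based early stopping, a
    probability-map to contour postprocessing chain, an Otsu thresholding
    baseline, spheroid morphometrics (mean diameter, spherical volume,
    circularity), a segmentation metric suite (Jaccard distance, relative
    diameter and circularity deviation, average radial error, invalid and
    ambiguous spheroid fractions) and interobserver agreement statistics
    (Friedman test with Dunn-Bonferroni post hoc comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
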