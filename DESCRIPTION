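Package: eelgrassArea
Title: Noise-Tolerant Leaf Area Estimation for Zostera marina from Digital Images
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates eelgrass (Zostera marina) leaf length, width and area
    from scanned leaf images whose contours are corrupted by humidity-induced
    noise. Implements tolerance-of-similarity region growing in RGB color
    space, peripheral contour extraction, pixel-count and Monte Carlo area
    estimators, and a statistical selection index that chooses the color
    tolerance minimizing leaf-area overestimation across a cohort of leaves
    grouped by length. Includes a synthetic leaf-image generator with ground
    truth and a parameterized humidity halo for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    png,
    jsonlite,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
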