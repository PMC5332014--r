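Package: wpbscreen
Title: High-Content Morphometry and Screen Scoring for Weibel-Palade Bodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis and screen-statistics workflow for
    high-content siRNA screens of Weibel-Palade body (WPB) morphology in
    endothelial cells. Segments nuclei on the Hoechst channel, approximates
    single-cell territories by Voronoi influence zones around nucleus
    centroids, segments rod-shaped WPBs on the von Willebrand factor channel
    by rolling-ball background subtraction and Bernsen local thresholding,
    extracts 24 per-object morphometric and intensity features (including
    Feret diameters by rotating calipers), aggregates four per-well
    statistics, normalizes plates by B-score median polish, computes robust
    Z scores, Z' factors and replicate reproducibility, and calls hits.
    Includes a synthetic plate generator with ground truth for end-to-end
    validation without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tiff,
    withr,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    jsonlite,
    optparse
Config/testthat/edition: 3
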