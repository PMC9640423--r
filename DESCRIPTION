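Package: ripaq
Title: Riparian Vegetation Quality Assessment from Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Object-based assessment of riparian strip quality from very
    high resolution multispectral satellite imagery. Provides a seeded
    simulator of WorldView-2-like scenes with ground truth, pansharpening,
    red-edge NDVI and principal-component compositing, multiresolution
    region-merging segmentation, hierarchical object classification with
    confusion-matrix accuracy and Cohen's kappa, per-station Riparian
    Strip Quality Index (RSQI) scoring with QBR field-index comparison,
    restoration triage, and agreement statistics. All results are tibbles
    so they compose with the tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    car,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse
Config/testthat/edition: 3
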