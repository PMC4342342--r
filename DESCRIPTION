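Package: colonymetrics
Title: Spatial Metrics and Filamentation Indices for Yeast Colony Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies non-uniform (filamentous and invasive) growth in
    two-dimensional binary images of microbial colonies. Implements three
    spatial metrics -- radial, angular and angular pair-correlation counts
    normalised against complete spatial randomness (CSR) -- on circular and
    annular lattice domains, discrete Fourier analysis of the angular
    signal with low-pass and dominant-mode filters, and four scalar
    indices of filamentation (radial, angular, pair-correlation and
    area-fraction). Includes synthetic pattern generators (uniform-random
    disks and annuli, regular cluster patterns, parametric filamentous
    colonies and growth time courses) used to validate the metrics, plus
    readers for binary raster masks and 4-D colony image stacks, CSV/JSON
    export and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
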