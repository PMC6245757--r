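Package: ecosuit
Title: Climate-Envelope Suitability Modelling for Medicinal Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of the GMPGIS climate-envelope
    pipeline for predicting global growing regions of medicinal plant
    species from occurrence records and ecological rasters: linear
    normalization of climate layers, range-based k-means clustering of
    occurrence climates, a rectangular-envelope distance surface
    intersected with suitable soil classes, spherical suitable-area
    accounting per administrative region, and a jackknife
    variable-contribution analysis. A companion phylogenetics component
    computes Kimura 2-parameter distances, neighbor-joining trees and
    bootstrap supports from aligned chloroplast marker sequences. A
    virtual-species scene generator (gradient climate fields, Voronoi
    soil mosaic, occurrences drawn from a known true envelope, sequence
    evolution under a two-rate substitution process) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
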