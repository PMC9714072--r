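Package: rhizotrack
Title: Automatic 2D+t Root System Architecture Reconstruction from
    Time-Lapse Plate Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the architecture and growth dynamics of seedling
    root systems from time-lapse series of 2D plate images. The pipeline
    registers the frames (block-matching rigid estimation plus an optional
    dense correction, composed in a daisy chain), detects per-pixel root
    apparition times by temporal change-point analysis, tracks organs
    through a weighted directed region adjacency graph (minimum spanning
    arborescence via Edmonds' algorithm, crossing resolution by iterated
    Hungarian matching, robust MADe artefact rejection), extracts timed
    centerlines (distance-map-weighted shortest paths, Douglas-Peucker
    decimation, seed and stopped-lateral extrapolation), and exports 2D+t
    models as RSML with per-node time annotations. Static and dynamic
    phenes (organ lengths, elongation rates, lateral counts, depth-binned
    elongation heatmaps, per-timestep group tests) are extracted as tidy
    tables. A synthetic root-growth image simulator with ground truth makes
    every stage testable without an acquisition platform.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    igraph,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
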