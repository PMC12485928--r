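Package: cellanchor
Title: Cell-to-Anchor Distance Graphs and Anchor-Centric Neighborhoods for
    Spatial Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cell-to-nearest-anchor-cell distance graphs from spatial
    single-cell tables (cell centroids plus cell-type labels), summarizes the
    resulting distance distributions per cell type and grouping, harmonizes
    free-text cell-type labels through a three-level typology crosswalked to
    Cell Ontology, and runs an anchor-cell-centric neighborhood pipeline:
    k-nearest-neighbor composition vectors, k-means neighborhood clustering
    with user-driven merging, radial (multi-window) composition analysis,
    subregion-normalized endothelial-cell enrichment, and donor-level
    association statistics.  A synthetic-tissue generator with known ground
    truth (vessel-anchored distance laws, planted neighborhood zones) makes
    every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    RANN,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    callr,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
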