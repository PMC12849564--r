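Package: cafniche
Title: Spatial Niche Analysis of Cancer-Associated Fibroblasts in Multiplex Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the spatial architecture of the tumor
    microenvironment from segmented multiplex immunohistochemistry data.
    Cells are phenotyped from marker mean intensities with a hierarchical
    sequential gating scheme (matrix and vascular cancer-associated
    fibroblast substates, endothelial, immune, tumor and myofibroblast
    cells), summarized into fixed-radius raster neighborhoods, clustered
    into tissue regions with a self-organizing map guided by the
    Davies-Bouldin index, and analyzed for region border interactions,
    pseudo-space composition gradients, and nearest-neighbor distances to
    vessels, immune and tumor cells. A synthetic tissue generator plants
    early- and late-stage niche architectures with full ground truth for
    validating every stage of the pipeline.
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
    jsonlite,
    mclust,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
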