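Package: nfcn
Title: Nearest Functionally Connected Neighbor Analysis for Single-Cell
    and Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies ligand-releasing cells that are functionally connected
    to receptor-bearing target cells in single-cell RNA-seq data and validates
    the inferred connections in spatially resolved transcriptomics. Implements
    the nearest functionally connected neighbor (NFCN) algorithm, which ranks
    candidate ligand cells and receiver cells along a kernel-smoothed
    interaction trajectory built from ligand/receptor expression and
    SVD-based enrichment of upstream-induction and downstream-activation gene
    programs, then pairs cells under confidence and spatial-proximity filters.
    Also provides the surrounding pipeline: CP10K log-normalization, variable
    gene selection, covariate regression and scaling, parallel-analysis
    component selection, shared-nearest-neighbor clustering, spatial surface
    matrices, four-program cellular state coordinates, autoencoder expression
    denoising with Bayesian robust correlation, Moran spatial statistics,
    distance-to-signature profiles, moving-average copy-number estimation,
    and a synthetic data generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    rjags,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
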