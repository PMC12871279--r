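Package: merscape
Title: Processing of Imaging-Based Spatial Transcriptomics Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for imaging-based spatial
    transcriptomics (MERFISH/MERSCOPE-style) sections at atlas scale.
    Builds a stain-like total-mRNA density image from transcript
    positions, tiles sections for pluggable 3D segmentation, assigns
    transcripts to cells and stitches tiles with an overlap merge rule,
    derives alpha-shape cell boundaries, computes per-cell quality
    metrics and fixed-threshold filters, flags doublets by quantile
    thresholding of singlet/doublet scores, adaptively filters
    label-transfer mapping scores per cell type with a double median
    absolute deviation rule and bimodality handling, prepares 30 um
    grid aggregations and clustering-stability analyses for spatial
    domain detection, applies QuickNII/VisuAlign alignment files to
    register cell centroids to a reference atlas, and scores imputed
    against measured expression with a multiscale structural similarity
    index over coarsened spatial graphs. A synthetic-data generator with
    known ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    FNN,
    igraph,
    jsonlite,
    matrixStats,
    rhdf5,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
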