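Package: rglineage
Title: Single-Cell Lineage Analysis of Adult Zebrafish Radial Glia Progeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control, pooled-deconvolution normalization, Louvain
    clustering, diffusion-map pseudotime, marker and differential-expression
    detection, neurogenic-commitment statistics and cross-species
    (zebrafish-mouse) cell-type homology mapping for plate-based single-cell
    RNA-seq of the adult zebrafish forebrain radial glia lineage. Includes a
    two-species synthetic count-data generator with planted populations,
    branching trajectory and orthologue structure so every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    glmnet,
    scran,
    sva,
    SingleCellExperiment,
    SummarizedExperiment,
    S4Vectors,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
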