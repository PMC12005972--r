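Package: cyclehcr
Title: Split-Barcode Multicycle HCR Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-detection analysis for split-barcode multicycle hybridization
    chain reaction (HCR) imaging of RNA and protein in thick tissue. Provides
    split L+R barcode codebook design and three-channel cycle scheduling,
    dilated-mask 3D spot-to-cell assignment into a genes-by-cells count matrix,
    false-positive estimation from non-targeting barcodes and gene/cell QC
    filtering, graph-based cell clustering with UMAP embedding and min-max
    scaled gene clustering, embryo-intrinsic axis transforms with left-right
    symmetry checks, per-cluster gradient regression and Spearman
    co-expression, midline segment slope classification, and
    reference-normalized nuclear protein quantification with ANOVA plus
    Bonferroni group comparisons. A synthetic-data generator emulating an
    egg-cylinder embryo and a layered hippocampal band provides ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    igraph,
    FNN,
    uwot,
    cluster,
    jsonlite,
    tiff,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
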