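# cyclehcr

Post-detection analysis for **split-barcode multicycle HCR imaging** of RNA
and protein in thick tissue (multiplexed in situ hybridization read out over
tens of three-channel imaging cycles). The package takes what the upstream
imaging stack produces — decoded single-molecule spot tables, 3D nucleus
label volumes, per-nucleus protein intensities — and turns them into
quantitative biology: a genes × cells count matrix, false-positive and
stability QC, spatial cell clusters, embryo-axis gradients, co-expression
structure, and normalized nuclear protein levels. A bundled synthetic-data
generator with full ground truth (an egg-cylinder embryo and a layered
hippocampal band) exercises every stage end to end.

## What it computes

**Codebook design and scheduling.** A target's identity is a
(channel, L, R) combination of split left/right readout barcodes; `n_L`
left and `n_R` right probes give `n_L × n_R` barcodes per channel
(30 × 30 = 900) and `n_L × n_R × n_ch` targets over `n_ch` channels
(2,700 at three). Targets are read out one per channel per cycle, so a
library of `G` targets needs `⌈G / n_ch⌉` cycles (254 genes + 12
non-targeting controls → 89; 120 genes → 40). `build_codebook()` allocates
collision-free barcodes reproducibly from a seed, reserves non-targeting
controls on rarely used half-sites, and `swap_barcodes()` supports the
barcode-swap control.

**Spot-to-cell assignment.** Nucleus masks are slightly dilated
(`dilate_labels()`, anisotropy-aware Euclidean distance with deterministic
nearest-label tie-breaks), spots take the label of their containing voxel
(`assign_spots()`), and counts are assembled into a `SingleCellExperiment`
with centroids and volumes in µm (`build_count_matrix()`).

**QC.** The conservative false-positive rate is
`max_c (total spots of control c) / n_cells`; a worst control at 200 spots
over 11,029 cells gives 0.018 spots per cell. Genes are active iff their
total count exceeds the control ceiling; low-count cells are flagged, not
dropped; detection-rate trends across cycles and nuclear-volume drift are
reported (`qc_report()`).

**Clustering and gradients.** Median-depth log-normalization, PCA → kNN
graph → Louvain communities with a UMAP embedding (`cluster_cells()`),
min-max scaled per-cluster gene profiles (`cluster_genes()`), kNN
imputation on the embedding, and marker-panel annotation. Cell positions
are transformed to embryo-intrinsic axes — distal-proximal distance along
the fitted midline, signed anterior-posterior angle (posterior = 0°,
left/right by sign), radial distance (`fit_midline()`,
`transform_coordinates()`) — and expression gradients are quantified per
cluster by OLS on min-max scaled expression vs. the scaled coordinate, so
slopes `k ∈ [−1, 1]` (`fit_gradient()`). Co-expression is pairwise Spearman
ρ within clusters (`coexpression_matrix()`); hippocampal bands are cut into
9 equal-arc-length midline segments with genes classified
descending/ascending/flat at `|k| ≥ 0.15` on the first 8 segments
(`classify_segments()`).

**Protein quantification.** Per-nucleus mean intensities
(`quantify_masks()`) are normalized to an inactive-chromatin reference
antigen (H3K27me3) per mask (`normalize_to_reference()`) and compared
across clusters by one-way ANOVA plus Bonferroni-adjusted pairwise Welch
tests against a reference cluster (`compare_groups()`), with
n.s. / * / ** / **** significance codes.

## Worked example

```r
library(cyclehcr)

barcode_capacity(30, 30, 1)   # 900
barcode_capacity(30, 30, 3)   # 2700

cb <- build_codebook(sprintf("gene%03d", 1:254), n_non_targeting = 12, seed = 1)
cb
#> codebook: 266 targets (12 non-targeting), 89 cycles, panels 30L x 30R x 3 channels

sim <- generate_embryo(seed = 1)
sim
#> cyclehcr_sim (embryo): 1440 cells, 135149 spots (393 background), 66 targets

dil <- dilate_labels(sim$labels, 1.0)
asn <- assign_spots(sim$spots, dil)
asn
#> spot_assignment: 134561 assigned, 588 unassigned (0 out of bounds)

sce  <- build_count_matrix(sim$spots, asn, sim$labels, sim$codebook)
norm <- normalize_counts(sce, filter_active_genes(sce))
cl   <- cluster_cells(norm, seed = 1)
cl
#> cluster_result: 9 clusters over 1440 cells (0 unallocated); sizes: 280, 240, 210, 190, 160, 110, 100, 100, 50
```

The nine recovered communities match the nine generating fate-map clusters
cell for cell (the sizes are exactly the configured cluster sizes), and
more than 99% of nucleus-origin spots are assigned to their true cell at
1.0 µm dilation. The
false-positive worked example:

```r
# worst non-targeting barcode: 200 spots across 11,029 cells
200 / 11029
#> 0.01813401   # ~0.018 false spots per cell
```

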