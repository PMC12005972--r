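---
title: "Models and methods behind the cyclehcr pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the cyclehcr pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The measurement being modelled

Split-barcode multicycle HCR imaging reads out hundreds of RNA species in
intact tissue by giving each target a combination of a left and a right
14-bp readout barcode within one of three fluorescence channels, imaging a
few targets per cycle and amplifying only where the matched L + R pair
binds adjacently. The upstream imaging stack (stitching, cross-cycle
registration, nucleus segmentation, single-molecule detection) is outside
this package; its outputs — decoded spot tables in physical coordinates,
3D nucleus label volumes with voxel-size metadata, per-nucleus protein
intensities — are this package's inputs.

## Codebook combinatorics

With $n_L$ left and $n_R$ right probes per channel and $n_{ch}$ channels,
the encoding capacity is $n_L \cdot n_R \cdot n_{ch}$: 900 barcodes per
channel and 2,700 targets over three channels at the default 30 × 30
panels. Cycle scheduling fills channels first, so $G$ targets need
$\lceil G / n_{ch} \rceil$ cycles. `build_codebook()` draws each channel's
(L, R) pairs from a seed-shuffled permutation of the full lattice and then
allocates sequentially — reproducible, collision-free by construction, and
free of systematic L/R reuse patterns. Non-targeting controls are drawn
from leftover combinations whose L and R half-sites are each used by at
most one targeting entry when enough headroom exists; because the controls
exist to estimate false positives, minimizing shared half-sites with real
probes is the conservative choice. How the original controls were chosen
relative to targeting L/R usage is not documented anywhere we could
follow, so this rule is a package design decision. Channel labels are
fixed to 488/561/640 nm; initiator chemistry is out of scope.

## Coordinate conventions

One convention is used everywhere: volumes are arrays indexed (x, y, z),
0-based voxel indices, physical coordinates in micrometres, and the voxel
of a point is `floor(coord / voxel_size)` per axis (points exactly on a
boundary belong to the higher voxel's predecessor — the floor side).
Centroids and volumes are always computed from the *undilated* volume.

## Dilated-mask spot assignment

`dilate_labels(labels, radius_um)` grows every label into background by at
most `radius_um` (Euclidean distance between voxel centres, anisotropic
voxel sizes respected). Pre-existing labels never change; a contested
background voxel goes to the label with the nearest pre-dilation labeled
voxel, exact ties to the smaller label id, making the operation fully
deterministic and matching a brute-force per-voxel nearest-label search
exactly (asserted in the tests). The default dilation radius is 1.0 µm:
"slightly dilated" masks capture spots in or near the nucleus while
minimizing contamination, and the radius is recorded in the output
metadata because the literature leaves its magnitude unquantified. A spot
falling where two dilated masks compete is resolved by the same
nearest-nucleus rule, and cells removed by QC keep their (flagged) column
so that assigned + unassigned always equals the number of spots.

## QC models

*False positives.* Non-targeting barcodes have no matching primary probe,
so their decoded spots estimate the false-positive floor. The estimator is
deliberately conservative: the **maximum** control total divided by the
cell count (0.018 per cell for a worst control of 200 spots over 11,029
cells), with the full per-control distribution reported.

*Active genes.* A gene is active iff its total count exceeds the control
ceiling — by default the observed maximum control total, with 200 as the
documented fallback. The thresholds behind published active-gene and
excluded-cell counts are not recoverable from main-text material, so both
thresholds are exposed parameters and recorded in the QC report;
`min_cell_total` defaults to 10 with cells at exactly the threshold
retained.

*Detection stability.* The per-cycle mean total count over active genes is
regressed on cycle number; detection is "stable" when the 95% CI of the
slope covers zero. At desk scale each cycle carries only one to three
genes, so the statistic confounds gene identity with cycle: on the
synthetic embryo, whose genes are scheduled in configuration order, the
trend reflects which genes landed in which cycle rather than efficiency
loss. The flag is meaningful when gene-to-cycle assignment is randomized
or gene count per cycle is large; the injected-decay recovery in the tests
uses fixtures constructed to isolate the efficiency signal.

## Clustering stack

Counts are depth-scaled to the median cell total and log1p-transformed
(zero-total cells flagged). Cells are reduced to 30 principal components,
joined by a Euclidean 15-nearest-neighbour graph, and partitioned by
Louvain modularity at resolution 1.0; the embedding is UMAP on the same
components. The clustering algorithm, neighbour count and resolution are
not pinned down by the published description (only UMAP is named), so the
package fixes standard single-cell defaults, requires an explicit seed,
and logs everything. "Unallocated" cells are operationalized as members of
communities smaller than `min_size = 20` plus cells with negative
silhouette width — the published criterion ("lacking clear cluster
association") is not stated, so this rule is ours. Gene profiles are
per-cluster means min-max scaled to [0, 1] per gene (constant genes scale
to 0 and are flagged), ordered by average-linkage hierarchical clustering
on correlation distance; embedding imputation is the mean over the k = 15
nearest embedding neighbours including self, a row-stochastic smoothing
that can never leave the input range.

## Embryo-intrinsic axes

The midline is the first principal axis of the interior (embryonic)
anchor-cluster centroids, oriented so the extraembryonic anchor projects
proximal-positive; the posterior reference is the perpendicular component
of a posterior anchor-cluster centroid. Both anchors are configurable
because the operational definition of the posterior line in the source
material is geometric only. Coordinates per cell: `dp` = projection onto
the midline, shifted so the distal-most cell is 0; `radial` =
perpendicular distance; `ap` = signed angle in (−180°, 180°] between the
perpendicular component and the posterior reference (posterior 0°,
right-hand rule about the proximal direction, right side = positive
angle). Cells exactly on the midline get `ap = 0` with a flag. The
transform is rigid-motion invariant up to the fitted-axis sign convention,
asserted numerically at 1e-6 in the tests. Curved (non-linear) embryo
midlines are a non-goal for the egg-cylinder case.

## Gradients, co-expression, segments

Gradient slopes are OLS coefficients after min-max scaling *both* the
per-cell expression and the axis coordinate over the cluster's cells, so
`slope_k` is dimensionless, lies in [−1, 1] for monotone bounded profiles,
and is invariant to affine rescaling of raw counts. This scaling matters
for threshold semantics: the published ±0.15 segment-slope threshold
implies normalized units, but the normalization itself is unstated, so the
package documents its choice prominently and does not claim comparability
with published gene tallies. Minimum 20 cells per cluster-axis fit, for
regression stability at desk scale.

Co-expression is pairwise Spearman ρ (average ranks) over a cluster's
cells, constant genes masked to 0, display order by hierarchical
clustering of 1 − ρ. The test suite checks the matrix against an explicit
rank-formula oracle at 1e-12 and asserts the qualitative decoupling the
analysis is designed to expose: two genes given identical axis gradients
but independent cell-level noise share slope sign while their |ρ| stays
low, whereas a latent-factor pair co-expresses strongly.

For hippocampal bands, cells are binned into 9 equal-arc-length segments
along a quadratic midline (arc length by dense sampling); per-gene segment
means over the first 8 segments are min-max scaled and regressed on the
scaled segment index, classifying genes descending / ascending / flat at
|k| ≥ 0.15. One caveat is inherent to this procedure: min-max scaling maps
*any* set of segment means onto [0, 1], so for a truly flat gene the
scaled means are pure noise and the fitted slope has a sampling SD near
0.35 regardless of expression level — flat genes therefore cannot be
reliably certified flat at the 0.15 threshold, and only the
strong-gradient designations are treated as recoverable ground truth.
Empty segments leave missing means; fits on fewer than 4 segments are
flagged.

## Protein quantification

Antigen levels are per-nucleus mean voxel intensities over the undilated
mask, normalized per cell to the inactive-chromatin reference antigen
(H3K27me3) so that local staining imbalances cancel; the ratio is
invariant to global intensity rescaling. Cells with zero or missing
reference are excluded with a flag. Whether published intensities were
background-subtracted before ratioing is unstated; the package ratios raw
mask means. Group comparisons run a one-way ANOVA followed by pairwise
Welch t-tests of each cluster against the reference cluster, raw p-values
multiplied by the number of comparisons (Bonferroni) and capped at 1. The
base pairwise test is Welch's t because "Bonferroni tests" does not name
one; Welch is the safe unequal-variance default. Significance codes follow
the boxplot-legend convention — n.s. (p > 0.05), ** (p < 0.01), ****
(p < 0.0001) — extended with * for p < 0.05 by standard convention since
the legend leaves the 0.01–0.05 band unnamed. Degenerate zero-variance
pairs get p = 1 when means are equal. Boxplot summaries export 10/90
whiskers, 25/75 box, median and mean.

## The synthetic-data generator

The generator produces the statistical and geometric structure the
downstream analysis assumes, with complete ground truth (per-cell cluster,
true counts, per-spot originating cell), and is byte-identical under a
fixed seed.

*Embryo geometry.* Nine clusters on a schematic egg cylinder (~200 µm
axis): an interior epiblast-like column, posterior and anterior interior
wings, a demarcation band, an extraembryonic cap, embryonic and
extraembryonic endoderm shells, a distal tip, and an outer parietal ring.
No quantitative embryo geometry (shell radii, cell density) is published,
so the layout is schematic and explicitly non-biological; left-right
symmetry holds in distribution because all regions are symmetric about the
midline-posterior plane. Nuclei are axis-aligned ellipsoids
(2.2 × 2.2 × 1.8 µm semiaxes, 10% radius jitter) placed by rejection
sampling with a minimum centre separation; this is sufficient to exercise
dilation and assignment without a full morphology model, and a geometry
too dense to place raises a placement error after bounded retries.

*Counts.* Per-cell counts are negative binomial — the standard
overdispersed model for the "salt and pepper" heterogeneity of early
fate specification, for which no explicit published model exists — with
mean `base_rate × exp(gradient_slope × axis_position) × exp(loading ×
latent_factor)`, dispersion `size = 5` by default. The desk-scale default
is 1,440 cells and 60 genes (five markers per cluster at rate 8, five
housekeeping at 3, four gradient carriers, four co-expression probes, two
silent) plus 6 non-targeting controls; a full-scale preset scales the same
layout to ~11,000 cells and 254 genes + 12 controls. Spots are uniform
inside each nucleus's ellipsoid expanded by a 0.4 µm margin; background
spots (the only source of non-targeting counts) are homogeneous Poisson
over the bounding volume at 0.3 expected spots per cell summed over all
barcodes. Per-spot intensities are log-normal (σ = 0.35 on the log scale)
scaled by per-channel amplification folds of 103.7, 88.3 and 121.3 for
488/561/640 nm. The default voxel size is 0.6 µm: coarse enough to keep
desk-scale volumes small, fine enough that the voxelized 1.0 µm dilation
ball is round rather than face-only, which is what lets margin spots
resolve to their true nucleus.

*Hippocampal band.* Three parallel cell layers (120 cells each) flank a
planar quadratic midline over a ~245 µm arc; each cell's normalized
arc-length position is recorded and drives monotone expression gradients
(designated strong descending/ascending sets at log-slope ∓1.6, flat
markers and housekeeping genes otherwise). Protein channels draw each
cell's reference-antigen intensity log-normally and each target antigen as
a per-cluster fold multiple of that same reference with independent
log-normal noise (σ = 0.15), so target/reference ratios concentrate at the
configured fold.

*What the generator does not emulate:* raw images, point-spread functions,
spot-detection errors, segmentation errors, optical depth effects,
cross-cycle misregistration, or real anatomical geometry. Passing tests
demonstrate that the algorithms recover known structure under the stated
statistical model — not that the model captures every failure mode of real
data.

## Problem sizes and numerical choices

Tests and the acceptance script run the desk-scale configurations: the
1,440-cell / 66-target embryo (three seeds for cluster recovery), the
360-cell / 44-target hippocampal band (five seeds for gradient
classification), exhaustive oracles on ≤ 32³ volumes and ≤ 8-cell
fixtures, and 1,000-replicate null simulations for the type-I error of
the group comparison. Distance ties in dilation use a 1e-9 tolerance;
angles are reported in degrees with the (−180°, 180°] branch; min-max
scaling of a constant vector returns 0 with a degeneracy flag everywhere
it can arise. All stochastic entry points take explicit seeds and restore
the caller's RNG state.

## Interfaces

Codebooks round-trip as tab-separated text; label volumes as multi-page
16-bit TIFF with a JSON voxel-size sidecar; spot tables, ground truth and
protein tables as CSV; count matrices as MatrixMarket + TSV metadata; QC
reports as JSON. The package is a library: the exported functions,
`scripts/acceptance.R`, and this vignette are the interface, and every
pipeline stage is a plain function call so shell wrappers are trivial to
add where a deployment needs them.
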