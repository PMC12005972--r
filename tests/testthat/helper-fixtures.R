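# shared fixtures and independent oracles, built in code at test time

.fixture_cache <- new.env(parent = emptyenv())

# default embryo simulation plus the downstream pipeline, memoised per seed
embryo_pipeline <- function(seed) {
  key <- paste0("embryo_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sim <- generate_embryo(seed = seed)
  dil <- dilate_labels(sim$labels, 1.0)
  asn <- assign_spots(sim$spots, dil)
  sce <- build_count_matrix(sim$spots, asn, sim$labels, sim$codebook)
  .fixture_cache[[key]] <- list(sim = sim, dilated = dil, assignment = asn,
                                sce = sce)
  .fixture_cache[[key]]
}

# a small three-cluster stacked-cylinder fate map for fast tests
tiny_fate_map <- function(n_cells = c(60, 50, 50), n_controls = 3,
                          background_rate_per_cell = 0.3, nb_size = 5,
                          gradient_slope = 0, seed = 1) {
  n_cells <- as.integer(n_cells)
  clusters <- list(
    list(name = "C1", type = "cylinder", r = c(0, 24), z = c(0, 40),  n = n_cells[1]),
    list(name = "C2", type = "cylinder", r = c(0, 24), z = c(45, 85), n = n_cells[2]),
    list(name = "C3", type = "cylinder", r = c(0, 24), z = c(90, 130), n = n_cells[3])
  )
  genes <- sprintf("t%02d", 1:12)
  controls <- sprintf("nontargeting_%02d", seq_len(n_controls))
  base <- matrix(0.3, 12, 3, dimnames = list(genes, c("C1", "C2", "C3")))
  markers <- list(C1 = genes[1:3], C2 = genes[4:6], C3 = genes[7:9])
  for (j in 1:3) base[markers[[j]], j] <- 8
  base[genes[10], ] <- 4            # gradient carrier
  base[genes[11], ] <- 3            # housekeeping
  base[genes[12], ] <- 0            # silent
  gradient <- matrix(0, 12, 3, dimnames = dimnames(base))
  gradient[genes[10], ] <- gradient_slope
  structure(list(
    kind = "embryo", preset = "tiny",
    clusters = clusters, genes = genes, controls = controls,
    markers = markers,
    base_rates = base, gradient_effects = gradient, gradient_axis = "dp",
    factor_loadings = matrix(0, 12, 3, dimnames = dimnames(base)),
    designations = list(silent = genes[12], gradient = genes[10]),
    nb_size = nb_size, background_rate_per_cell = background_rate_per_cell,
    nucleus_semiaxes_um = c(2.2, 2.2, 1.8), radius_jitter = 0.1,
    spot_margin_um = 0.4, voxel_size_um = c(0.6, 0.6, 0.6),
    channel_gain = c(`488` = 103.7, `561` = 88.3, `640` = 121.3),
    intensity_sdlog = 0.35, padding_um = 5, seed = as.integer(seed)
  ), class = "fate_map_config")
}

# wrap a plain counts matrix as the SingleCellExperiment the modules consume
counts_to_sce <- function(counts, is_control = grepl("^nontargeting",
                                                     rownames(counts))) {
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(
      cell = seq_len(ncol(counts)),
      qc_excluded = FALSE, qc_zero_total = FALSE,
      row.names = as.character(seq_len(ncol(counts)))),
    rowData = S4Vectors::DataFrame(gene = rownames(counts),
                                   is_control = is_control, active = NA,
                                   row.names = rownames(counts)))
}

# brute-force dilation oracle: per background voxel, search every labeled
# voxel within the radius; nearest wins, ties to the smaller label
dilate_oracle <- function(vol, radius_um) {
  a <- vol$data
  vs <- vol$voxel_size_um
  d <- dim(a)
  src <- which(a > 0L)
  sx <- ((src - 1L) %% d[1]) * vs[1]
  sy <- (((src - 1L) %/% d[1]) %% d[2]) * vs[2]
  sz <- ((src - 1L) %/% (d[1] * d[2])) * vs[3]
  lab <- a[src]
  out <- a
  for (v in which(a == 0L)) {
    vx <- ((v - 1L) %% d[1]) * vs[1]
    vy <- (((v - 1L) %/% d[1]) %% d[2]) * vs[2]
    vz <- ((v - 1L) %/% (d[1] * d[2])) * vs[3]
    dd <- sqrt((sx - vx)^2 + (sy - vy)^2 + (sz - vz)^2)
    ok <- dd <= radius_um + 1e-9
    if (!any(ok)) next
    best <- min(dd[ok])
    cand <- lab[ok][abs(dd[ok] - best) <= 1e-9]
    out[v] <- min(cand)
  }
  label_volume(out, vs)
}

# Spearman oracle: Pearson product-moment formula applied to average ranks,
# written out as explicit sums
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# adjusted Rand index against ground truth (closed-form pair counting)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  sc <- function(v) sum(choose(v, 2))
  idx <- sc(as.vector(tab))
  e1 <- sc(rowSums(tab)); e2 <- sc(colSums(tab))
  expected <- e1 * e2 / choose(sum(tab), 2)
  (idx - expected) / ((e1 + e2) / 2 - expected)
}
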