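#' Default egg-cylinder embryo fate-map configuration
#'
#' Describes the synthetic embryo the generator emulates: an egg-cylinder of
#' nine spatially segregated expression clusters — interior embryonic columns
#' (C1 epiblast-like, C2 posterior and C3 anterior wings), a demarcation band
#' (C4), an extraembryonic cap (C5), enclosing endoderm shells (C6, C7) and
#' distal tip (C9), and an outer parietal ring (C8) — with per-cluster marker
#' programs, axial log-linear gradients, shared latent co-expression factors,
#' left-right symmetric geometry, and homogeneous Poisson background spots.
#' Counts are negative binomial (overdispersed "salt and pepper"
#' heterogeneity). Geometry is schematic, not measured anatomy.
#'
#' The desk preset places ~1,440 nuclei with 60 genes plus 6 non-targeting
#' controls; the full preset scales the same layout to ~11,000 nuclei and 254
#' genes plus 12 controls.
#'
#' @param preset `"desk"` (default) or `"full"`.
#' @param background_rate_per_cell Expected false (background) spots per cell,
#'   summed over all barcodes (default 0.3).
#' @param nb_size Negative-binomial size (dispersion) parameter (default 5).
#' @param seed Integer seed stored in the configuration.
#' @return A `fate_map_config` list; see Details for fields.
#' @export
embryo_fate_map <- function(preset = c("desk", "full"),
                            background_rate_per_cell = 0.3,
                            nb_size = 5, seed = 1) {
  preset <- match.arg(preset)
  gscale <- if (preset == "full") 2 else 1        # geometry scale
  cscale <- if (preset == "full") 7.6 else 1      # cell-count scale
  s <- function(v) v * gscale
  clusters <- list(
    list(name = "C1", type = "cylinder", r = s(c(0, 32)),  z = s(c(10, 70)),   n = 280),
    list(name = "C2", type = "cylinder", r = s(c(0, 32)),  z = s(c(70, 110)),  n = 100, y_min = s(4)),
    list(name = "C3", type = "cylinder", r = s(c(0, 32)),  z = s(c(70, 110)),  n = 100, y_max = s(-4)),
    list(name = "C4", type = "cylinder", r = s(c(34, 46)), z = s(c(95, 120)),  n = 110),
    list(name = "C5", type = "cylinder", r = s(c(0, 40)),  z = s(c(145, 195)), n = 240),
    list(name = "C6", type = "cylinder", r = s(c(34, 46)), z = s(c(5, 95)),    n = 190),
    list(name = "C7", type = "cylinder", r = s(c(34, 46)), z = s(c(120, 195)), n = 160),
    list(name = "C8", type = "cylinder", r = s(c(50, 62)), z = s(c(0, 200)),   n = 210),
    list(name = "C9", type = "cylinder", r = s(c(0, 34)),  z = s(c(0, 10)),    n = 50)
  )
  for (i in seq_along(clusters)) {
    clusters[[i]]$n <- as.integer(round(clusters[[i]]$n * cscale))
  }
  n_clusters <- length(clusters)

  if (preset == "desk") {
    n_markers_per <- 5L; n_hk <- 5L; n_controls <- 6L
  } else {
    n_markers_per <- 25L; n_hk <- 13L; n_controls <- 12L
  }
  n_grad <- 4L; n_coex <- 4L; n_silent <- 2L
  n_genes <- n_markers_per * n_clusters + n_hk + n_grad + n_coex + n_silent
  genes <- sprintf("g%03d", seq_len(n_genes))
  controls <- sprintf("nontargeting_%02d", seq_len(n_controls))

  base <- matrix(0.2, n_genes, n_clusters,
                 dimnames = list(genes, vapply(clusters, `[[`, "", "name")))
  markers <- vector("list", n_clusters)
  names(markers) <- colnames(base)
  k <- 0L
  for (j in seq_len(n_clusters)) {
    idx <- k + seq_len(n_markers_per); k <- k + n_markers_per
    base[idx, j] <- 8
    markers[[j]] <- genes[idx]
  }
  hk <- k + seq_len(n_hk); k <- k + n_hk
  base[hk, ] <- 3
  grad_genes <- genes[k + seq_len(n_grad)]; k <- k + n_grad
  base[grad_genes, ] <- 4
  coex_genes <- genes[k + seq_len(n_coex)]; k <- k + n_coex
  base[coex_genes, ] <- 3
  silent <- genes[k + seq_len(n_silent)]
  base[silent, ] <- 0

  # log-linear slopes vs the cell's scaled distal-proximal position within
  # its cluster's axial extent
  gradient <- matrix(0, n_genes, n_clusters, dimnames = dimnames(base))
  gradient[grad_genes[1], c(1, 5)] <- 1.5
  gradient[grad_genes[2], c(1, 6)] <- -1.5
  gradient[grad_genes[3], c(2, 3)] <- 1.0
  # two genes share a gradient but have independent cell-level noise
  gradient[coex_genes[3], 1] <- 0.8
  gradient[coex_genes[4], 1] <- 0.8

  # one latent factor per cluster; a correlated gene pair in C1
  loadings <- matrix(0, n_genes, n_clusters, dimnames = dimnames(base))
  loadings[coex_genes[1], 1] <- 0.9
  loadings[coex_genes[2], 1] <- 0.9

  structure(list(
    kind = "embryo", preset = preset,
    clusters = clusters,
    genes = genes, controls = controls,
    markers = markers,
    base_rates = base, gradient_effects = gradient, gradient_axis = "dp",
    factor_loadings = loadings,
    designations = list(gradient = grad_genes, coexpressed = coex_genes[1:2],
                        shared_gradient = coex_genes[3:4], silent = silent,
                        housekeeping = genes[hk]),
    nb_size = nb_size,
    background_rate_per_cell = background_rate_per_cell,
    nucleus_semiaxes_um = s(1) * c(2.2, 2.2, 1.8), radius_jitter = 0.1,
    spot_margin_um = 0.4,
    voxel_size_um = c(0.6, 0.6, 0.6) * gscale,
    channel_gain = c(`488` = 103.7, `561` = 88.3, `640` = 121.3),
    intensity_sdlog = 0.35,
    padding_um = s(5),
    seed = as.integer(seed)
  ), class = "fate_map_config")
}

#' @export
print.fate_map_config <- function(x, ...) {
  cat(sprintf("fate_map_config (%s, %s): %d clusters, %d cells, %d genes + %d controls\n",
              x$kind, x$preset %||% "custom", length(x$clusters),
              sum(vapply(x$clusters, `[[`, 0L, "n")),
              length(x$genes), length(x$controls)))
  invisible(x)
}

# ---- internal placement/rasterization machinery ---------------------------

# uniform sample in an annular cylinder cross-section, optional y half-plane
sample_region <- function(cl, n) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 32L)
    r <- sqrt(stats::runif(m, cl$r[1]^2, cl$r[2]^2))
    th <- stats::runif(m, 0, 2 * pi)
    x <- r * cos(th); y <- r * sin(th)
    z <- stats::runif(m, cl$z[1], cl$z[2])
    keep <- rep(TRUE, m)
    if (!is.null(cl$y_min)) keep <- keep & y >= cl$y_min
    if (!is.null(cl$y_max)) keep <- keep & y <= cl$y_max
    out <- rbind(out, cbind(x, y, z)[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# sequential placement with a minimum centre separation, via a uniform grid
place_cells <- function(clusters, sep_min, max_tries_per_cell = 200L) {
  n_total <- sum(vapply(clusters, `[[`, 0L, "n"))
  centers <- matrix(NA_real_, n_total, 3)
  cluster_of <- integer(n_total)
  grid <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(g) paste(g, collapse = ",")
  placed <- 0L
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    got <- 0L; tries <- 0L
    budget <- max_tries_per_cell * cl$n
    while (got < cl$n) {
      if (tries >= budget) {
        stop(sprintf("placement error: could not place %d cells in cluster %s (geometry too dense)",
                     cl$n, cl$name), call. = FALSE)
      }
      batch <- sample_region(cl, min(cl$n - got + 16L, 256L))
      for (b in seq_len(nrow(batch))) {
        tries <- tries + 1L
        p <- batch[b, ]
        g <- floor(p / sep_min)
        ok <- TRUE
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          nb <- grid[[key(g + c(dx, dy, dz))]]
          if (!is.null(nb)) {
            d2 <- colSums((t(centers[nb, , drop = FALSE]) - p)^2)
            if (any(d2 < sep_min^2)) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) {
          placed <- placed + 1L; got <- got + 1L
          centers[placed, ] <- p
          cluster_of[placed] <- ci
          kk <- key(g)
          grid[[kk]] <- c(grid[[kk]], placed)
          if (got >= cl$n) break
        }
      }
    }
  }
  list(centers = centers, cluster = cluster_of)
}

# rasterize axis-aligned ellipsoids into an integer label array
rasterize_nuclei <- function(centers, semiaxes, dims, voxel_size) {
  a <- array(0L, dim = dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  for (i in seq_len(nrow(centers))) {
    c0 <- centers[i, ]; r0 <- semiaxes[i, ]
    i0 <- pmax(floor((c0 - r0) / voxel_size), 0)
    i1 <- pmin(floor((c0 + r0) / voxel_size), dims - 1)
    if (any(i1 < i0)) next
    xs <- ((i0[1]:i1[1]) + 0.5) * voxel_size[1] - c0[1]
    ys <- ((i0[2]:i1[2]) + 0.5) * voxel_size[2] - c0[2]
    zs <- ((i0[3]:i1[3]) + 0.5) * voxel_size[3] - c0[3]
    m <- outer(outer((xs / r0[1])^2, (ys / r0[2])^2, "+"), (zs / r0[3])^2, "+") <= 1
    blk <- a[(i0[1]:i1[1]) + 1L, (i0[2]:i1[2]) + 1L, (i0[3]:i1[3]) + 1L, drop = FALSE]
    blk[m & blk == 0L] <- i
    a[(i0[1]:i1[1]) + 1L, (i0[2]:i1[2]) + 1L, (i0[3]:i1[3]) + 1L] <- blk
  }
  a
}

# uniform points inside an axis-aligned ellipsoid
runif_ellipsoid <- function(n, center, semiaxes) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(ceiling(2.2 * (n - nrow(out))) + 8L, 16L)
    u <- matrix(stats::runif(3L * m, -1, 1), m, 3)
    keep <- rowSums(u^2) <= 1
    out <- rbind(out, u[keep, , drop = FALSE])
  }
  sweep(out[seq_len(n), , drop = FALSE], 2L, semiaxes, "*") +
    matrix(center, n, 3, byrow = TRUE)
}

# draw counts, place spots, add background; shared by both generators.
# axis_pos: per-cell coordinate in [0,1] driving gradient_effects.
simulate_spots <- function(config, codebook, centers, semiaxes, cluster_of,
                           axis_pos, dims_um) {
  genes <- config$genes; controls <- config$controls
  all_targets <- c(genes, controls)
  n_cells <- nrow(centers)
  n_genes <- length(genes)

  latent <- stats::rnorm(n_cells)
  mu <- config$base_rates[, cluster_of, drop = FALSE] *
    exp(config$gradient_effects[, cluster_of, drop = FALSE] *
          matrix(axis_pos, n_genes, n_cells, byrow = TRUE)) *
    exp(config$factor_loadings[, cluster_of, drop = FALSE] *
          matrix(latent, n_genes, n_cells, byrow = TRUE))
  counts <- matrix(stats::rnbinom(length(mu), size = config$nb_size, mu = mu),
                   n_genes, n_cells, dimnames = list(genes, NULL))

  margin <- config$spot_margin_um
  per_cell <- colSums(counts)
  spot_xyz <- matrix(NA_real_, sum(per_cell), 3)
  spot_gene <- character(sum(per_cell))
  spot_cell <- integer(sum(per_cell))
  pos <- 0L
  for (i in seq_len(n_cells)) {
    k <- per_cell[i]
    if (k == 0L) next
    pts <- runif_ellipsoid(k, centers[i, ], semiaxes[i, ] + margin)
    rows <- pos + seq_len(k)
    spot_xyz[rows, ] <- pts
    spot_gene[rows] <- rep(genes, counts[, i])
    spot_cell[rows] <- i
    pos <- pos + k
  }

  n_bg <- stats::rpois(1L, config$background_rate_per_cell * n_cells)
  if (n_bg > 0L) {
    bg_xyz <- cbind(stats::runif(n_bg, 0, dims_um[1]),
                    stats::runif(n_bg, 0, dims_um[2]),
                    stats::runif(n_bg, 0, dims_um[3]))
    bg_gene <- sample(all_targets, n_bg, replace = TRUE)
    spot_xyz <- rbind(spot_xyz, bg_xyz)
    spot_gene <- c(spot_gene, bg_gene)
    spot_cell <- c(spot_cell, integer(n_bg))
  }

  ch <- codebook$channel[match(spot_gene, codebook$target)]
  cyc <- codebook$cycle[match(spot_gene, codebook$target)]
  gain <- config$channel_gain[as.character(ch)]
  intensity <- gain * stats::rlnorm(length(spot_gene), 0, config$intensity_sdlog)

  spots <- data.frame(
    x_um = spot_xyz[, 1], y_um = spot_xyz[, 2], z_um = spot_xyz[, 3],
    channel = ch, cycle = cyc, gene = spot_gene, intensity = intensity,
    stringsAsFactors = FALSE
  )
  true_counts <- rbind(counts,
                       matrix(0L, length(controls), n_cells,
                              dimnames = list(controls, NULL)))
  list(spots = spots, spot_cell = spot_cell, true_counts = true_counts)
}

#' Generate a synthetic egg-cylinder embryo dataset
#'
#' Places non-overlapping ellipsoidal nuclei on the nested egg-cylinder
#' geometry of the configuration, draws per-cell negative-binomial transcript
#' counts whose means combine cluster base rates, axial log-linear gradients
#' and shared latent factors, scatters each cell's spots uniformly inside its
#' slightly expanded nucleus, and adds homogeneous Poisson background spots
#' (the only source of counts for non-targeting barcodes). Per-spot
#' intensities are log-normal, scaled by the per-channel HCR amplification
#' folds (103.7 / 88.3 / 121.3 for 488 / 561 / 640 nm). Fully reproducible
#' from the seed.
#'
#' @param config A [embryo_fate_map()] configuration.
#' @param codebook Optional codebook covering the configuration's genes and
#'   controls; built automatically (same seed) when `NULL`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `cyclehcr_sim` list: `labels` ([label_volume()]), `spots`
#'   (data.frame: x_um, y_um, z_um, channel, cycle, gene, intensity), `truth`
#'   (per-cell cluster/centroid/side/axis position, true genes x cells count
#'   matrix, per-spot originating cell with 0 = background), `codebook`, and
#'   `config`.
#' @export
generate_embryo <- function(config = embryo_fate_map(), codebook = NULL,
                            seed = config$seed) {
  stopifnot(inherits(config, "fate_map_config"), config$kind == "embryo")
  if (is.null(codebook)) {
    codebook <- build_codebook(config$genes,
                               n_non_targeting = length(config$controls),
                               seed = seed)
  }
  missing <- setdiff(c(config$genes, config$controls), codebook$target)
  if (length(missing)) {
    stop("codebook does not cover: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  r_max <- max(vapply(config$clusters, function(cl) cl$r[2], 0)) +
    max(config$nucleus_semiaxes_um)
  z_max <- max(vapply(config$clusters, function(cl) cl$z[2], 0))
  pad <- config$padding_um
  offset <- c(r_max + pad, r_max + pad, pad)
  dims_um <- c(2 * (r_max + pad), 2 * (r_max + pad), z_max + 2 * pad)
  sep_min <- 2 * max(config$nucleus_semiaxes_um) * (1 + config$radius_jitter) +
    2 * config$spot_margin_um + 0.2

  res <- with_seed(seed, {
    pl <- place_cells(config$clusters, sep_min)
    n_cells <- nrow(pl$centers)
    jit <- matrix(stats::runif(3L * n_cells, 1 - config$radius_jitter,
                               1 + config$radius_jitter), n_cells, 3)
    semiaxes <- jit * matrix(config$nucleus_semiaxes_um, n_cells, 3, byrow = TRUE)
    centers <- sweep(pl$centers, 2L, offset, "+")

    # scaled distal-proximal position within the cell's own cluster extent
    axis_pos <- numeric(n_cells)
    for (ci in seq_along(config$clusters)) {
      zr <- config$clusters[[ci]]$z
      sel <- pl$cluster == ci
      axis_pos[sel] <- (pl$centers[sel, 3] - zr[1]) / (zr[2] - zr[1])
    }

    sim <- simulate_spots(config, codebook, centers, semiaxes, pl$cluster,
                          axis_pos, dims_um)
    dims <- ceiling(dims_um / config$voxel_size_um)
    vol <- rasterize_nuclei(centers, semiaxes, dims, config$voxel_size_um)

    # left/right by the sign convention of the axis transform: midline +z,
    # posterior +y, right-hand rule => right side is x < 0
    side <- ifelse(pl$centers[, 1] < 0, "right", "left")
    cells <- data.frame(
      cell = seq_len(n_cells),
      cluster = vapply(config$clusters, `[[`, "", "name")[pl$cluster],
      x_um = centers[, 1], y_um = centers[, 2], z_um = centers[, 3],
      dp_pos = axis_pos, side = side,
      stringsAsFactors = FALSE
    )
    list(labels = label_volume(vol, config$voxel_size_um),
         spots = sim$spots,
         truth = list(cells = cells, counts = sim$true_counts,
                      spot_cell = sim$spot_cell,
                      axis_origin = offset,
                      axis_direction = c(0, 0, 1),
                      posterior_direction = c(0, 1, 0)))
  })
  structure(c(res, list(codebook = codebook, config = config)),
            class = "cyclehcr_sim")
}

#' @export
print.cyclehcr_sim <- function(x, ...) {
  cat(sprintf("cyclehcr_sim (%s): %d cells, %d spots (%d background), %d targets\n",
              x$config$kind, nrow(x$truth$cells), nrow(x$spots),
              sum(x$truth$spot_cell == 0L), nrow(x$codebook)))
  invisible(x)
}

#' Default layered hippocampal band configuration
#'
#' A curved band of three parallel cell layers following a planar quadratic
#' midline, with a configurable subset of genes carrying monotone arc-length
#' gradients (strong descending / ascending designations for parameter
#' recovery), flat cluster markers and housekeeping genes, and per-nucleus
#' protein channels generated per cluster against a fixed inactive-chromatin
#' reference antigen (H3K27me3).
#'
#' @inheritParams embryo_fate_map
#' @return A `fate_map_config` list with `kind = "hippocampus"`.
#' @export
hippocampus_band <- function(background_rate_per_cell = 0.3, nb_size = 5,
                             seed = 1) {
  n_per_layer <- 120L
  clusters <- list(
    list(name = "C1", offset = c(-21, -7), n = n_per_layer),
    list(name = "C2", offset = c(-7, 7),   n = n_per_layer),
    list(name = "C3", offset = c(7, 21),   n = n_per_layer)
  )
  genes <- sprintf("h%03d", 1:40)
  controls <- sprintf("nontargeting_%02d", 1:4)
  base <- matrix(3, 40, 3, dimnames = list(genes, c("C1", "C2", "C3")))
  desc <- genes[1:6]; asc <- genes[7:10]
  base[c(desc, asc), ] <- 5
  markers <- list(C1 = genes[11:16], C2 = genes[17:22], C3 = genes[23:28])
  for (j in 1:3) {
    base[markers[[j]], ] <- 0.3
    base[markers[[j]], j] <- 6
  }
  gradient <- matrix(0, 40, 3, dimnames = dimnames(base))
  gradient[desc, ] <- -1.6
  gradient[asc, ] <- 1.6

  structure(list(
    kind = "hippocampus",
    clusters = clusters,
    midline_coef = c(0, 0, 0.0012),          # y = c0 + c1 x + c2 x^2
    x_range = c(-120, 120), z_range = c(0, 24),
    genes = genes, controls = controls, markers = markers,
    base_rates = base, gradient_effects = gradient, gradient_axis = "arc",
    factor_loadings = matrix(0, 40, 3, dimnames = dimnames(base)),
    designations = list(descending = desc, ascending = asc,
                        flat = genes[29:40]),
    antigens = c("H3K27ac", "H3K4me1", "Nup98"),
    reference_antigen = "H3K27me3",
    protein_folds = matrix(c(1.0, 1.5, 0.7,
                             1.0, 1.2, 1.2,
                             1.0, 0.9, 1.3), 3, 3, byrow = TRUE,
                           dimnames = list(c("H3K27ac", "H3K4me1", "Nup98"),
                                           c("C1", "C2", "C3"))),
    protein_reference_mean = 1000, protein_sdlog = 0.15,
    nb_size = nb_size,
    background_rate_per_cell = background_rate_per_cell,
    nucleus_semiaxes_um = c(2.2, 2.2, 1.8), radius_jitter = 0.1,
    spot_margin_um = 0.4,
    voxel_size_um = c(0.6, 0.6, 0.6),
    channel_gain = c(`488` = 103.7, `561` = 88.3, `640` = 121.3),
    intensity_sdlog = 0.35,
    padding_um = 5,
    seed = as.integer(seed)
  ), class = "fate_map_config")
}

# cumulative arc length of the quadratic midline, by dense sampling
midline_arc <- function(coef, x_range, n = 2048L) {
  xs <- seq(x_range[1], x_range[2], length.out = n)
  ys <- coef[1] + coef[2] * xs + coef[3] * xs^2
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  list(x = xs, y = ys, s = c(0, cumsum(seg)))
}

#' Generate a synthetic hippocampal band dataset with protein channels
#'
#' Cells are placed in three layers flanking a planar quadratic midline; each
#' cell's arc-length position along the midline is recorded in the ground
#' truth and drives the configured monotone expression gradients. Per-nucleus
#' protein intensities are drawn per cluster as log-normal multiples of a
#' cell-specific reference-antigen intensity, so target/reference ratios
#' concentrate at the configured fold.
#'
#' @param config A [hippocampus_band()] configuration.
#' @param codebook Optional codebook; built automatically when `NULL`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `cyclehcr_sim` list as for [generate_embryo()], plus `protein`
#'   (data.frame: cell, antigen, mean_intensity; includes the reference
#'   antigen rows) and per-cell arc positions in `truth$cells$arc_s`.
#' @export
generate_hippocampus <- function(config = hippocampus_band(), codebook = NULL,
                                 seed = config$seed) {
  stopifnot(inherits(config, "fate_map_config"), config$kind == "hippocampus")
  if (is.null(codebook)) {
    codebook <- build_codebook(config$genes,
                               n_non_targeting = length(config$controls),
                               seed = seed)
  }
  arc <- midline_arc(config$midline_coef, config$x_range)
  total_len <- max(arc$s)
  sep_min <- 2 * max(config$nucleus_semiaxes_um) * (1 + config$radius_jitter) +
    2 * config$spot_margin_um + 0.2

  res <- with_seed(seed, {
    # sample arc position uniformly, offset along the local normal
    centers <- NULL; cluster_of <- NULL; arc_s <- NULL
    grid <- new.env(hash = TRUE, parent = emptyenv())
    key <- function(g) paste(g, collapse = ",")
    pts <- list()
    for (ci in seq_along(config$clusters)) {
      cl <- config$clusters[[ci]]
      got <- 0L; tries <- 0L; budget <- 200L * cl$n
      while (got < cl$n) {
        if (tries >= budget) {
          stop("placement error: hippocampal band too dense", call. = FALSE)
        }
        tries <- tries + 1L
        s0 <- stats::runif(1, 0, total_len)
        i <- findInterval(s0, arc$s, all.inside = TRUE)
        x0 <- arc$x[i]; y0 <- arc$y[i]
        slope <- config$midline_coef[2] + 2 * config$midline_coef[3] * x0
        nrm <- c(-slope, 1) / sqrt(1 + slope^2)
        off <- stats::runif(1, cl$offset[1], cl$offset[2])
        p <- c(x0 + off * nrm[1], y0 + off * nrm[2],
               stats::runif(1, config$z_range[1], config$z_range[2]))
        g <- floor(p / sep_min); ok <- TRUE
        for (dx in -1:1) { for (dy in -1:1) { for (dz in -1:1) {
          nb <- grid[[key(g + c(dx, dy, dz))]]
          if (!is.null(nb)) {
            prev <- do.call(rbind, pts[nb])
            if (any(colSums((t(prev) - p)^2) < sep_min^2)) { ok <- FALSE; break }
          }
        }; if (!ok) break }; if (!ok) break }
        if (ok) {
          pts[[length(pts) + 1L]] <- p
          kk <- key(g); grid[[kk]] <- c(grid[[kk]], length(pts))
          cluster_of <- c(cluster_of, ci)
          arc_s <- c(arc_s, s0 / total_len)
          got <- got + 1L
        }
      }
    }
    centers <- do.call(rbind, pts)
    n_cells <- nrow(centers)

    # shift to non-negative coordinates
    pad <- config$padding_um + max(config$nucleus_semiaxes_um)
    offset <- -apply(centers, 2, min) + pad
    centers <- sweep(centers, 2L, offset, "+")
    dims_um <- apply(centers, 2, max) + pad

    jit <- matrix(stats::runif(3L * n_cells, 1 - config$radius_jitter,
                               1 + config$radius_jitter), n_cells, 3)
    semiaxes <- jit * matrix(config$nucleus_semiaxes_um, n_cells, 3, byrow = TRUE)

    sim <- simulate_spots(config, codebook, centers, semiaxes, cluster_of,
                          arc_s, dims_um)
    dims <- ceiling(dims_um / config$voxel_size_um)
    vol <- rasterize_nuclei(centers, semiaxes, dims, config$voxel_size_um)

    cl_names <- vapply(config$clusters, `[[`, "", "name")
    cells <- data.frame(
      cell = seq_len(n_cells), cluster = cl_names[cluster_of],
      x_um = centers[, 1], y_um = centers[, 2], z_um = centers[, 3],
      arc_s = arc_s, stringsAsFactors = FALSE
    )

    # protein channels: reference intensity per cell, targets as per-cluster
    # log-normal fold multiples of it
    ref <- stats::rlnorm(n_cells, log(config$protein_reference_mean),
                         config$protein_sdlog)
    prot <- data.frame(cell = seq_len(n_cells),
                       antigen = config$reference_antigen,
                       mean_intensity = ref, stringsAsFactors = FALSE)
    for (ag in config$antigens) {
      fold <- config$protein_folds[ag, cluster_of]
      val <- fold * ref * stats::rlnorm(n_cells, 0, config$protein_sdlog)
      prot <- rbind(prot, data.frame(cell = seq_len(n_cells), antigen = ag,
                                     mean_intensity = val,
                                     stringsAsFactors = FALSE))
    }

    list(labels = label_volume(vol, config$voxel_size_um),
         spots = sim$spots,
         truth = list(cells = cells, counts = sim$true_counts,
                      spot_cell = sim$spot_cell),
         protein = prot)
  })
  structure(c(res, list(codebook = codebook, config = config)),
            class = "cyclehcr_sim")
}

#' Write a simulated dataset to plain-text files
#'
#' Label volume as multi-page TIFF (+ JSON voxel-size sidecar), spot table and
#' ground truth as CSV, codebook as TSV, protein table as CSV when present.
#'
#' @param sim A [generate_embryo()] / [generate_hippocampus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_volume(sim$labels, file.path(dir, "labels.tif"))
  utils::write.csv(sim$spots, file.path(dir, "spots.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(spot = seq_along(sim$truth$spot_cell),
                              cell = sim$truth$spot_cell,
                              gene = sim$spots$gene),
                   file.path(dir, "truth_spots.csv"), row.names = FALSE)
  write_codebook(sim$codebook, file.path(dir, "codebook.tsv"))
  if (!is.null(sim$protein)) {
    utils::write.csv(sim$protein, file.path(dir, "protein.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read / write spot tables
#'
#' CSV with columns x_um, y_um, z_um, channel, cycle, gene, intensity.
#'
#' @param path CSV path.
#' @return Data frame of spots.
#' @export
read_spots <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
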