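#' Per-cluster expression gradient along an intrinsic axis
#'
#' Ordinary least squares of per-cell expression against an axis coordinate,
#' both min-max scaled to [0, 1] over the cluster's cells, so the slope
#' `slope_k` is dimensionless and lies in [-1, 1] for monotone bounded
#' profiles: +1 is a perfectly linear ascending profile, -1 descending. The
#' scaling makes `slope_k` invariant to affine rescaling of the raw counts.
#' Constant expression gives slope 0 with a degenerate flag.
#'
#' @param expression Numeric per-cell expression for one gene.
#' @param coordinate Numeric per-cell axis coordinate (same cells).
#' @param min_cells Minimum cells required (default 20).
#' @return A `gradient_fit` one-row data.frame: slope_k, intercept, r2,
#'   n_cells, degenerate.
#' @export
fit_gradient <- function(expression, coordinate, min_cells = 20) {
  n <- length(expression)
  if (n != length(coordinate)) stop("length mismatch", call. = FALSE)
  if (n < min_cells) {
    stop(sprintf("cluster has %d cells; %d required", n, min_cells),
         call. = FALSE)
  }
  y <- minmax_scale(expression)
  x <- minmax_scale(coordinate)
  if (isTRUE(attr(y, "degenerate")) || isTRUE(attr(x, "degenerate"))) {
    return(data.frame(slope_k = 0, intercept = mean(as.numeric(y)), r2 = NA_real_,
                      n_cells = n, degenerate = TRUE))
  }
  fit <- stats::lm.fit(cbind(1, as.numeric(x)), as.numeric(y))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  data.frame(slope_k = unname(fit$coefficients[2]),
             intercept = unname(fit$coefficients[1]),
             r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
             n_cells = n, degenerate = FALSE)
}

#' Gradient fits for many genes across clusters and axes
#'
#' Convenience wrapper running [fit_gradient()] for every requested
#' (gene, cluster, axis) combination; clusters with fewer than `min_cells`
#' members are skipped.
#'
#' @param sce Count matrix (uses the `counts` assay).
#' @param axes An [transform_coordinates()] result aligned with columns.
#' @param clusters Per-cell cluster labels (`NA` allowed).
#' @param genes Genes to fit (default all non-control).
#' @param axis_names Axis columns of `axes` to use (default dp, ap, radial).
#' @param min_cells Minimum cluster size (default 20).
#' @return Data frame: gene, cluster, axis, slope_k, intercept, r2, n_cells,
#'   degenerate.
#' @export
fit_gradients <- function(sce, axes, clusters, genes = NULL,
                          axis_names = c(dp = "dp_um", ap = "ap_deg",
                                         radial = "radial_um"),
                          min_cells = 20) {
  if (is.null(genes)) {
    genes <- rownames(sce)[!SummarizedExperiment::rowData(sce)$is_control]
  }
  counts <- SummarizedExperiment::assay(sce, "counts")
  out <- list()
  for (k in sort(unique(clusters[!is.na(clusters)]))) {
    sel <- !is.na(clusters) & clusters == k
    if (sum(sel) < min_cells) next
    for (ax in names(axis_names)) {
      coord <- axes[[axis_names[[ax]]]][sel]
      for (g in genes) {
        f <- fit_gradient(as.numeric(counts[g, sel]), coord, min_cells)
        f$gene <- g; f$cluster <- k; f$axis <- ax
        out[[length(out) + 1L]] <- f
      }
    }
  }
  res <- do.call(rbind, out)
  res[, c("gene", "cluster", "axis", "slope_k", "intercept", "r2",
          "n_cells", "degenerate")]
}

#' Rank genes by gradient slope
#'
#' Stable sort from positive-ascending to negative-descending, ties broken
#' by gene name, so the output is invariant to input row order.
#'
#' @param fits A [fit_gradients()] table (one cluster-axis combination, or
#'   any subset).
#' @return The table sorted by decreasing `slope_k`.
#' @export
rank_genes_by_slope <- function(fits) {
  fits[order(-fits$slope_k, fits$gene), , drop = FALSE]
}

#' Spearman co-expression matrix within a cluster
#'
#' Pairwise Spearman rank correlation of gene counts over a cluster's cells
#' (average ranks for ties). Constant genes have undefined correlations,
#' stored as 0 with a mask flag; genes are ordered by hierarchical
#' clustering of `1 - rho` (average linkage) for display.
#'
#' @param sce Count matrix.
#' @param clusters Per-cell cluster labels.
#' @param cluster The cluster to analyse.
#' @param genes Genes to include (default all non-control).
#' @return A `coexpression_matrix`: list with `rho` (symmetric, unit
#'   diagonal), `mask` (TRUE where rho was undefined), `order`, `cluster`,
#'   `n_cells`.
#' @export
coexpression_matrix <- function(sce, clusters, cluster, genes = NULL) {
  if (is.null(genes)) {
    genes <- rownames(sce)[!SummarizedExperiment::rowData(sce)$is_control]
  }
  sel <- !is.na(clusters) & clusters == cluster
  if (sum(sel) < 3L) stop("need at least 3 cells in the cluster", call. = FALSE)
  x <- t(as.matrix(
    SummarizedExperiment::assay(sce, "counts")[genes, sel, drop = FALSE]))
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  mask <- outer(const, const, "|") & !diag(TRUE, length(genes))
  rho[!is.finite(rho)] <- 0
  rho[mask] <- 0
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2                     # exact symmetry
  ord <- seq_along(genes)
  if (length(genes) > 2L) {
    hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
    ord <- hc$order
  }
  structure(list(rho = rho, mask = mask, order = genes[ord],
                 cluster = cluster, n_cells = sum(sel)),
            class = "coexpression_matrix")
}

#' @export
print.coexpression_matrix <- function(x, ...) {
  cat(sprintf("coexpression_matrix: cluster %s, %d genes over %d cells\n",
              x$cluster, nrow(x$rho), x$n_cells))
  invisible(x)
}

#' Classify gene gradients along midline segments
#'
#' Cells are binned into `n_segments` equal-arc-length segments along the
#' band's midline; for each gene the mean transcript count per cell is
#' computed per segment, the first `n_fit` segment means are min-max scaled
#' and regressed against the segment index scaled to [0, 1], and the gene is
#' classified descending (`slope_k <= -k_threshold`), ascending
#' (`slope_k >= k_threshold`) or flat. Defaults follow the 9-segment layout
#' with the fit on the first 8 segments and threshold 0.15. Empty segments
#' yield missing means; the regression uses the available segments and is
#' flagged when fewer than 4 remain.
#'
#' @param sce Count matrix.
#' @param arc_positions Per-cell arc-length position (any monotone scale).
#' @param cells_in_band Logical or index vector selecting the band's cells
#'   (default all).
#' @param n_segments,n_fit,k_threshold Defaults 9, 8, 0.15.
#' @param genes Genes to classify (default all non-control).
#' @return List: `per_gene` (data.frame gene, slope_k, class, n_segments_used,
#'   flagged), `segment_means` (genes x segments), `segment_counts`.
#' @export
classify_segments <- function(sce, arc_positions, cells_in_band = NULL,
                              n_segments = 9, n_fit = 8, k_threshold = 0.15,
                              genes = NULL) {
  if (n_fit > n_segments) stop("'n_fit' must be <= 'n_segments'", call. = FALSE)
  if (is.null(genes)) {
    genes <- rownames(sce)[!SummarizedExperiment::rowData(sce)$is_control]
  }
  counts <- SummarizedExperiment::assay(sce, "counts")[genes, , drop = FALSE]
  if (is.null(cells_in_band)) cells_in_band <- seq_len(ncol(counts))
  counts <- counts[, cells_in_band, drop = FALSE]
  s <- arc_positions[cells_in_band]
  if (length(s) != ncol(counts)) stop("arc positions do not match cells", call. = FALSE)

  brk <- seq(min(s), max(s), length.out = n_segments + 1L)
  seg <- findInterval(s, brk, rightmost.closed = TRUE, all.inside = TRUE)
  seg_counts <- tabulate(seg, n_segments)

  means <- matrix(NA_real_, length(genes), n_segments,
                  dimnames = list(genes, paste0("S", seq_len(n_segments))))
  for (j in seq_len(n_segments)) {
    if (seg_counts[j] > 0) {
      means[, j] <- Matrix::rowMeans(counts[, seg == j, drop = FALSE])
    }
  }

  per <- data.frame(gene = genes, slope_k = NA_real_, class = "flat",
                    n_segments_used = 0L, flagged = FALSE,
                    stringsAsFactors = FALSE)
  xall <- (seq_len(n_fit) - 1) / (n_fit - 1)
  for (g in seq_along(genes)) {
    y <- means[g, seq_len(n_fit)]
    ok <- !is.na(y)
    per$n_segments_used[g] <- sum(ok)
    per$flagged[g] <- sum(ok) < 4L
    if (sum(ok) < 2L) next
    ys <- minmax_scale(y[ok])
    if (isTRUE(attr(ys, "degenerate"))) { per$slope_k[g] <- 0; next }
    xs <- minmax_scale(xall[ok])
    fit <- stats::lm.fit(cbind(1, as.numeric(xs)), as.numeric(ys))
    k <- unname(fit$coefficients[2])
    per$slope_k[g] <- k
    per$class[g] <- if (k <= -k_threshold) "descending"
      else if (k >= k_threshold) "ascending" else "flat"
  }
  list(per_gene = per, segment_means = means, segment_counts = seg_counts)
}
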