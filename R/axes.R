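#' Fit the embryo midline from anchor-cluster centroids
#'
#' The midline is the first principal axis of the centroids of the interior
#' (embryonic) anchor clusters, oriented so the centroid of the
#' extraembryonic anchor cluster projects to the positive (proximal) end.
#'
#' @param centroids n x 3 matrix of cell centroids (micrometres).
#' @param cluster_labels Per-cell cluster labels (any type).
#' @param anchor_clusters Labels of the interior clusters defining the axis.
#' @param orient_cluster Label of the extraembryonic cluster fixing the
#'   proximal direction; `NULL` leaves the PCA sign as-is.
#' @return List: `point` (axis base point), `direction` (unit vector,
#'   proximal-positive).
#' @export
fit_midline <- function(centroids, cluster_labels = NULL,
                        anchor_clusters = NULL, orient_cluster = NULL) {
  centroids <- as.matrix(centroids)
  sel <- if (is.null(anchor_clusters)) rep(TRUE, nrow(centroids)) else
    cluster_labels %in% anchor_clusters
  pts <- centroids[sel, , drop = FALSE]
  if (nrow(pts) < 3L) stop("need at least 3 anchor cells", call. = FALSE)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  if (sv$d[1] - sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("orientation-ambiguous: isotropic centroid covariance", call. = FALSE)
  }
  u <- sv$v[, 1]
  if (!is.null(orient_cluster)) {
    oc <- colMeans(centroids[cluster_labels %in% orient_cluster, , drop = FALSE])
    if (sum((oc - ctr) * u) < 0) u <- -u
  }
  list(point = ctr, direction = u / sqrt(sum(u^2)))
}

#' Transform cell positions to embryo-intrinsic axes
#'
#' Decomposes each centroid relative to the midline into: `dp_um`, the
#' distance along the midline (distal = 0, increasing proximal; offset so
#' the distal-most cell is at 0); `radial_um`, the perpendicular distance to
#' the midline; and `ap_deg`, the signed angle in (-180, 180] degrees
#' between the cell's perpendicular component and the posterior reference
#' direction (posterior = 0, anterior = +/-180), with sign by the right-hand
#' rule about the proximal-pointing midline. Cells are divided into left and
#' right sides by the sign of the angle (right iff `ap_deg > 0`); a cell
#' exactly on the midline has an undefined angle, recorded as 0 and flagged.
#'
#' @param centroids n x 3 matrix of centroids (micrometres).
#' @param midline A [fit_midline()] result.
#' @param posterior_reference Direction (length-3) pointing posterior; must
#'   not be parallel to the midline. Typically the perpendicular component
#'   of a posterior anchor-cluster centroid.
#' @return An `embryo_axes` data.frame: cell, dp_um, ap_deg, radial_um,
#'   side, on_midline.
#' @export
transform_coordinates <- function(centroids, midline, posterior_reference) {
  centroids <- as.matrix(centroids)
  u <- midline$direction / sqrt(sum(midline$direction^2))
  q <- as.numeric(posterior_reference)
  q <- q - sum(q * u) * u                      # perpendicularize
  qn <- sqrt(sum(q^2))
  if (qn < 1e-12) {
    stop("posterior reference is parallel to the midline", call. = FALSE)
  }
  q <- q / qn
  v <- sweep(centroids, 2L, midline$point)
  t_par <- as.numeric(v %*% u)
  perp <- v - outer(t_par, u)
  radial <- sqrt(rowSums(perp^2))
  on_mid <- radial < 1e-9
  # signed angle between perp and q about u
  cx <- cbind(q[2] * perp[, 3] - q[3] * perp[, 2],
              q[3] * perp[, 1] - q[1] * perp[, 3],
              q[1] * perp[, 2] - q[2] * perp[, 1])
  ap <- atan2(as.numeric(cx %*% u), as.numeric(perp %*% q)) * 180 / pi
  ap[on_mid] <- 0
  ap[ap <= -180] <- 180                        # angle in (-180, 180]
  out <- data.frame(
    cell = seq_len(nrow(centroids)),
    dp_um = t_par - min(t_par),
    ap_deg = ap,
    radial_um = radial,
    side = ifelse(on_mid, NA_character_, ifelse(ap > 0, "right", "left")),
    on_midline = on_mid,
    stringsAsFactors = FALSE
  )
  class(out) <- c("embryo_axes", "data.frame")
  out
}

#' Left-right expression symmetry
#'
#' Per-gene mean counts on the left and right sides of the embryo and the
#' Pearson correlation over genes — mirrored halves of a bilaterally
#' symmetric embryo should express near-identically, so a high correlation
#' validates that imaging depth does not bias detection.
#'
#' @param sce Count matrix.
#' @param axes An [transform_coordinates()] result aligned with `sce`
#'   columns.
#' @param genes Optional gene subset (default all non-control genes).
#' @return List: `per_gene` (data.frame gene, mean_left, mean_right), `r`
#'   (`NA` with `defined = FALSE` when fewer than 2 genes).
#' @export
left_right_correlation <- function(sce, axes, genes = NULL) {
  if (is.null(genes)) {
    genes <- rownames(sce)[!SummarizedExperiment::rowData(sce)$is_control]
  }
  counts <- SummarizedExperiment::assay(sce, "counts")[genes, , drop = FALSE]
  left <- which(axes$side == "left")
  right <- which(axes$side == "right")
  if (!length(left) || !length(right)) {
    stop("both sides must be non-empty", call. = FALSE)
  }
  per <- data.frame(
    gene = genes,
    mean_left = Matrix::rowMeans(counts[, left, drop = FALSE]),
    mean_right = Matrix::rowMeans(counts[, right, drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  defined <- nrow(per) >= 2L && stats::sd(per$mean_left) > 0 &&
    stats::sd(per$mean_right) > 0
  list(per_gene = per,
       r = if (defined) stats::cor(per$mean_left, per$mean_right) else NA_real_,
       defined = defined)
}
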