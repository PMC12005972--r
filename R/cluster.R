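#' Depth-normalize and log-transform counts
#'
#' Scales each cell's counts to the median total count across cells, then
#' applies `log(1 + x)`. Deterministic; zero-count cells become zero vectors
#' and are flagged in `colData(sce)$qc_zero_total`. The normalized matrix is
#' stored as assay `"lognorm"`.
#'
#' @param sce Count matrix from [build_count_matrix()].
#' @param genes Optional gene subset (e.g. the active set) to normalize over;
#'   default all genes.
#' @return The `SingleCellExperiment` with an added `lognorm` assay.
#' @export
normalize_counts <- function(sce, genes = NULL) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (!is.null(genes)) {
    sce <- sce[genes, ]
    counts <- counts[genes, , drop = FALSE]
  }
  totals <- Matrix::colSums(counts)
  zero <- totals == 0
  target <- stats::median(totals[!zero])
  if (!is.finite(target) || target <= 0) target <- 1
  sf <- ifelse(zero, 1, totals / target)
  norm <- log1p(t(t(as.matrix(counts)) / sf))
  SummarizedExperiment::assay(sce, "lognorm") <- norm
  SummarizedExperiment::colData(sce)$qc_zero_total <- zero
  sce
}

#' Cluster cells on a kNN graph with a UMAP embedding
#'
#' Cells are reduced by PCA (default 30 components) on their normalized
#' profiles, connected by a k-nearest-neighbour graph (Euclidean), and
#' partitioned by Louvain community detection at the given resolution; the
#' 2D embedding is UMAP on the same principal components. Cells in
#' communities smaller than `min_size`, or with negative silhouette width
#' against their assigned cluster, are marked unallocated (`NA`). Cluster
#' labels are relabelled 1..K by decreasing size.
#'
#' @param sce Normalized matrix ([normalize_counts()]).
#' @param k_neighbors Neighbours for the graph and UMAP (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param seed Integer seed (mandatory: graph clustering and UMAP are
#'   stochastic).
#' @param n_pcs Principal components retained (default 30).
#' @param min_size Minimum cluster size before members are unallocated
#'   (default 20).
#' @param use_silhouette Also unallocate cells with silhouette < 0
#'   (default TRUE).
#' @return A `cluster_result`: list with `cluster` (integer per cell, `NA`
#'   unallocated), `embedding` (n x 2), `sizes`, `n_clusters`, `pca`.
#' @export
cluster_cells <- function(sce, k_neighbors = 15, resolution = 1, seed,
                          n_pcs = 30, min_size = 20, use_silhouette = TRUE) {
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  x <- t(SummarizedExperiment::assay(sce, "lognorm"))
  n <- nrow(x)
  if (n < k_neighbors + 1) {
    stop("need at least k_neighbors + 1 cells", call. = FALSE)
  }
  if (all(apply(x, 2, stats::sd) == 0)) {
    warning("all cells identical; returning a single cluster")
    emb <- matrix(0, n, 2)
    return(structure(list(cluster = rep(1L, n), embedding = emb,
                          sizes = c(`1` = n), n_clusters = 1L, pca = NULL),
                     class = "cluster_result"))
  }

  with_seed(seed, {
    keep <- apply(x, 2, stats::sd) > 0
    pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
                        rank. = min(n_pcs, sum(keep), n - 1))
    scores <- pc$x

    nn <- FNN::get.knn(scores, k = k_neighbors)
    edges <- cbind(rep(seq_len(n), k_neighbors), as.vector(nn$nn.index))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    memb <- igraph::membership(comm)

    emb <- uwot::umap(scores, n_neighbors = k_neighbors, n_threads = 1,
                      n_sgd_threads = 0)

    cl <- as.integer(memb)
    sizes <- table(cl)
    small <- as.integer(names(sizes)[sizes < min_size])
    unalloc <- cl %in% small
    if (use_silhouette && length(unique(cl[!unalloc])) > 1L) {
      sil <- cluster::silhouette(cl, stats::dist(scores))
      unalloc <- unalloc | sil[, "sil_width"] < 0
    }
    cl[unalloc] <- NA_integer_
    # contiguous labels 1..K by decreasing size
    tab <- sort(table(cl), decreasing = TRUE)
    cl <- match(as.character(cl), names(tab))
    sizes <- table(cl)
    names(sizes) <- as.character(seq_along(sizes))
    structure(list(cluster = cl, embedding = emb,
                   sizes = sizes, n_clusters = length(sizes),
                   pca = scores),
              class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters over %d cells (%d unallocated); sizes: %s\n",
              x$n_clusters, length(x$cluster), sum(is.na(x$cluster)),
              paste(as.integer(x$sizes), collapse = ", ")))
  invisible(x)
}

#' Cluster genes on min-max scaled cluster means
#'
#' Computes each gene's mean normalized expression per cell cluster, min-max
#' scales it across clusters to [0, 1] (so every non-constant gene attains
#' both 0 and 1), and orders genes by hierarchical clustering (average
#' linkage on correlation distance) for display. Constant genes are scaled
#' to all-zero and flagged.
#'
#' @param sce Normalized matrix.
#' @param clusters A [cluster_cells()] result or an integer vector of
#'   per-cell cluster labels (`NA` = unallocated).
#' @return List: `scaled_means` (genes x clusters, in [0,1]), `means` (raw),
#'   `order` (gene display order), `degenerate` (constant-gene flags).
#' @export
cluster_genes <- function(sce, clusters) {
  cl <- if (inherits(clusters, "cluster_result")) clusters$cluster else clusters
  x <- SummarizedExperiment::assay(sce, "lognorm")
  ks <- sort(unique(cl[!is.na(cl)]))
  means <- vapply(ks, function(k) rowMeans(x[, !is.na(cl) & cl == k, drop = FALSE]),
                  numeric(nrow(x)))
  colnames(means) <- as.character(ks)
  scaled <- t(apply(means, 1, function(v) as.numeric(minmax_scale(v))))
  dimnames(scaled) <- dimnames(means)
  degenerate <- apply(means, 1, function(v) diff(range(v)) == 0)
  ord <- seq_len(nrow(scaled))
  if (nrow(scaled) > 2L) {
    cc <- suppressWarnings(stats::cor(t(scaled)))
    cc[!is.finite(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    ord <- hc$order
  }
  list(scaled_means = scaled, means = means,
       order = rownames(scaled)[ord], degenerate = degenerate)
}

#' Smooth expression over embedding neighbours
#'
#' Replaces each cell's value by the mean over its `k` nearest neighbours in
#' the 2D embedding (self included) — the imputation used to visualize where
#' a gene is over-represented on the UMAP. A row-stochastic smoothing:
#' imputed values stay within the range of the input.
#'
#' @param values Numeric vector (one gene) or matrix (genes x cells).
#' @param embedding n x 2 embedding coordinates.
#' @param k Neighbours including self (default 15); `k = 1` is the identity.
#' @return Smoothed values, same shape as the input.
#' @export
impute_on_embedding <- function(values, embedding, k = 15) {
  vec <- is.null(dim(values))
  m <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  n <- ncol(m)
  if (nrow(embedding) != n) stop("embedding size mismatch", call. = FALSE)
  k <- min(k, n)
  if (k == 1L) return(values)
  nn <- FNN::get.knn(embedding, k = k - 1L)$nn.index
  idx <- cbind(seq_len(n), nn)
  out <- m
  for (g in seq_len(nrow(m))) {
    v <- m[g, ]
    out[g, ] <- rowMeans(matrix(v[idx], nrow = n))
  }
  if (vec) as.numeric(out) else out
}

#' Score marker-panel hypotheses against cluster profiles
#'
#' For each cell cluster, finds the annotation hypothesis whose marker genes
#' have the highest mean min-max scaled expression in that cluster, and
#' reports the margin to the runner-up.
#'
#' @param scaled_means Genes x clusters matrix from [cluster_genes()].
#' @param panel Named list: hypothesis -> character vector of marker genes.
#' @return Data frame: cluster, hypothesis, score, margin.
#' @export
score_markers <- function(scaled_means, panel) {
  if (length(panel) == 0L) stop("empty marker panel", call. = FALSE)
  miss <- setdiff(unlist(panel), rownames(scaled_means))
  if (length(miss)) {
    stop("markers absent from the expression matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  scores <- vapply(panel, function(gs) {
    colMeans(scaled_means[gs, , drop = FALSE])
  }, numeric(ncol(scaled_means)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(colnames(scaled_means),
                                                             names(panel)))
  best <- apply(scores, 1, which.max)
  margin <- apply(scores, 1, function(v) {
    s <- sort(v, decreasing = TRUE)
    if (length(s) > 1) s[1] - s[2] else s[1]
  })
  data.frame(cluster = rownames(scores),
             hypothesis = colnames(scores)[best],
             score = scores[cbind(seq_len(nrow(scores)), best)],
             margin = margin,
             stringsAsFactors = FALSE, row.names = NULL)
}
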