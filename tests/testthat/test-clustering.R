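lognorm_sce <- function(mat) {
  colnames(mat) <- as.character(seq_len(ncol(mat)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(lognorm = mat),
    colData = S4Vectors::DataFrame(cell = seq_len(ncol(mat)),
                                   row.names = colnames(mat)))
}

test_that("depth normalization rescales to the median total then log-transforms", {
  counts <- cbind(c(2, 2, 4), c(4, 4, 8), c(0, 0, 0))
  dimnames(counts) <- list(c("g1", "g2", "g3"), NULL)
  # equal-depth cells (1 and 2 scaled): cell 3 is all-zero and flagged
  sce <- normalize_counts(counts_to_sce(counts))
  norm <- SummarizedExperiment::assay(sce, "lognorm")
  expect_true(all(norm[, 3] == 0))
  expect_true(SummarizedExperiment::colData(sce)$qc_zero_total[3])
  # doubling a cell's counts leaves its normalized profile unchanged
  expect_equal(norm[, 1], norm[, 2])
  # equal-depth input reduces to pure log1p
  eq <- matrix(c(1, 3, 2, 2, 0, 4), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), NULL))
  n2 <- SummarizedExperiment::assay(normalize_counts(counts_to_sce(eq)),
                                    "lognorm")
  expect_equal(n2, log1p(eq), ignore_attr = TRUE)
})

test_that("two well-separated blobs are recovered perfectly", {
  x <- withr::with_seed(1, cbind(
    matrix(rnorm(30 * 30), 30),
    matrix(rnorm(30 * 30, mean = 12), 30)))
  rownames(x) <- paste0("g", 1:30)
  res <- cluster_cells(lognorm_sce(x), seed = 1, min_size = 5)
  expect_equal(res$n_clusters, 2)
  expect_equal(ari(res$cluster, rep(1:2, each = 30)), 1)
  # vanishing resolution collapses connected data to a single cluster
  x2 <- withr::with_seed(2, cbind(
    matrix(rnorm(30 * 30), 30),
    matrix(rnorm(30 * 30, mean = 1.5), 30)))
  rownames(x2) <- paste0("g", 1:30)
  res0 <- cluster_cells(lognorm_sce(x2), resolution = 1e-4, seed = 1,
                        min_size = 5, use_silhouette = FALSE)
  expect_equal(res0$n_clusters, 1)
})

test_that("identical cells produce a single cluster with a warning", {
  x <- matrix(1, 10, 40, dimnames = list(paste0("g", 1:10), NULL))
  expect_warning(res <- cluster_cells(lognorm_sce(x), seed = 1), "identical")
  expect_equal(res$n_clusters, 1)
})

test_that("cluster labels are contiguous, size-ordered and permutation-stable", {
  cfg <- tiny_fate_map(seed = 8)
  sim <- generate_embryo(cfg, seed = 8)
  sce <- normalize_counts(counts_to_sce(sim$truth$counts))
  res <- cluster_cells(sce, seed = 8, min_size = 10)
  expect_equal(res$n_clusters, 3)
  expect_gte(ari(res$cluster, sim$truth$cells$cluster), 0.9)
  got <- sort(unique(res$cluster[!is.na(res$cluster)]))
  expect_equal(got, seq_len(res$n_clusters))
  expect_true(all(diff(as.integer(res$sizes)) <= 0))
  # reordering cells permutes labels identically (up to label names)
  perm <- withr::with_seed(3, sample(ncol(sce)))
  res_p <- cluster_cells(sce[, perm], seed = 8, min_size = 10)
  expect_equal(ari(res_p$cluster, res$cluster[perm]), 1)
})

test_that("gene clustering min-max scales cluster means and orders blocks together", {
  cfg <- tiny_fate_map(seed = 8)
  sim <- generate_embryo(cfg, seed = 8)
  sce <- normalize_counts(counts_to_sce(sim$truth$counts))
  cl <- match(sim$truth$cells$cluster, c("C1", "C2", "C3"))
  gc <- cluster_genes(sce, cl)
  expect_true(all(gc$scaled_means >= 0 & gc$scaled_means <= 1))
  # every non-constant gene attains both 0 and 1 across clusters
  for (g in rownames(gc$scaled_means)[!gc$degenerate]) {
    expect_equal(min(gc$scaled_means[g, ]), 0)
    expect_equal(max(gc$scaled_means[g, ]), 1)
  }
  # a gene expressed in one cluster only scales to an indicator
  expect_equal(unname(gc$scaled_means["t01", ]), c(1, 0, 0), tolerance = 0.15)
  # constant (silent) gene flagged and scaled to zero
  expect_true(gc$degenerate[["t12"]])
  expect_true(all(gc$scaled_means["t12", ] == 0))
  # same-block markers end up adjacent in the display order
  for (j in 1:3) {
    pos <- match(cfg$markers[[j]], gc$order)
    expect_lte(max(pos) - min(pos), length(pos))
  }
})

test_that("embedding imputation is a range-preserving neighbourhood mean", {
  emb <- withr::with_seed(2, matrix(rnorm(200), 100, 2))
  v <- withr::with_seed(3, rnorm(100))
  expect_identical(impute_on_embedding(v, emb, k = 1), v)
  expect_equal(impute_on_embedding(rep(2, 100), emb, k = 15), rep(2, 100))
  sm <- impute_on_embedding(v, emb, k = 15)
  expect_true(all(sm >= min(v) & sm <= max(v)))

  # a cluster-restricted gene stays over-represented in its cluster after
  # smoothing, at close to the generating fold change: three well-separated
  # blobs so neighbourhoods are cluster-pure
  withr::with_seed(12, {
    blob <- rbind(cbind(rnorm(100, 0, 2), rnorm(100, 0, 2)),
                  cbind(rnorm(100, 50, 2), rnorm(100, 0, 2)),
                  cbind(rnorm(100, 0, 2), rnorm(100, 50, 2)))
    inC1 <- rep(c(TRUE, FALSE, FALSE), each = 100)
    raw <- ifelse(inC1, rnbinom(300, size = 5, mu = 8),
                  rnbinom(300, size = 5, mu = 1))
    imp <- impute_on_embedding(raw, blob, k = 15)
    fold_imp <- mean(imp[inC1]) / mean(imp[!inC1])
    expect_lt(abs(fold_imp - 8) / 8, 0.2)
  })
})

test_that("marker scoring annotates clusters and rejects empty panels", {
  sm <- matrix(0, 6, 3, dimnames = list(paste0("g", 1:6), c("1", "2", "3")))
  sm[1:2, 1] <- 1; sm[3:4, 2] <- 1; sm[5:6, 3] <- 1
  res <- score_markers(sm, list(epiblast = c("g1", "g2"),
                                endoderm = c("g3", "g4"),
                                extraembryonic = c("g5", "g6")))
  expect_equal(res$hypothesis, c("epiblast", "endoderm", "extraembryonic"))
  expect_true(all(res$margin == 1))
  expect_error(score_markers(sm, list()), "empty")
  expect_error(score_markers(sm, list(a = "missing_gene")), "absent")

  # synthetic fate map: every cluster annotated by its own marker set
  cfg <- tiny_fate_map(seed = 8)
  sim <- generate_embryo(cfg, seed = 8)
  sce <- normalize_counts(counts_to_sce(sim$truth$counts))
  cl <- match(sim$truth$cells$cluster, c("C1", "C2", "C3"))
  gc <- cluster_genes(sce, cl)
  ann <- score_markers(gc$scaled_means, cfg$markers)
  expect_equal(ann$hypothesis, c("C1", "C2", "C3"))
})
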