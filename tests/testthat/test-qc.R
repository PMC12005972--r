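test_that("the false-positive rate is the worst control total per cell", {
  # worked example: a worst control with 200 spots over 11,029 cells
  counts <- Matrix::sparseMatrix(
    i = c(rep(1, 5), rep(2, 200)),
    j = c(1:5, seq_len(200)),
    x = 1, dims = c(3, 11029),
    dimnames = list(c("geneA", "nontargeting_01", "nontargeting_02"),
                    as.character(seq_len(11029))))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(
      gene = rownames(counts),
      is_control = c(FALSE, TRUE, TRUE)))
  fp <- estimate_false_positive_rate(sce)
  expect_equal(round(fp$fp_rate_per_cell, 3), 0.018)
  expect_equal(fp$per_control[["nontargeting_01"]], 200)
  expect_equal(fp$per_control[["nontargeting_02"]], 0)

  # zero control spots, and the missing-control error
  sce0 <- counts_to_sce(matrix(0, 2, 10, dimnames = list(
    c("g1", "nontargeting_01"), NULL)))
  expect_equal(estimate_false_positive_rate(sce0)$fp_rate_per_cell, 0)
  sce_nc <- counts_to_sce(matrix(1, 1, 10, dimnames = list("g1", NULL)))
  expect_error(estimate_false_positive_rate(sce_nc), "control")

  # invariant to permutations of cells and of control labels
  px <- embryo_pipeline(1)
  perm <- withr::with_seed(2, sample(ncol(px$sce)))
  expect_equal(estimate_false_positive_rate(px$sce[, perm])$fp_rate_per_cell,
               estimate_false_positive_rate(px$sce)$fp_rate_per_cell)
})

test_that("the false-positive estimate matches the max-order-statistic expectation", {
  # background-only controls: each control total is Poisson with rate
  # bg_rate * n_cells / n_targets; the estimator is max/n_cells. Compare one
  # pipeline estimate against a 1,000-replicate Monte-Carlo oracle.
  cfg <- tiny_fate_map(n_controls = 20, background_rate_per_cell = 0.05,
                       seed = 13)
  sim <- generate_embryo(cfg, seed = 13)
  sce <- counts_to_sce(sim$truth$counts)
  # decoded control totals = their background draws
  ctrl_totals <- table(factor(sim$spots$gene[sim$truth$spot_cell == 0],
                              levels = cfg$controls))
  cnt <- as.matrix(sim$truth$counts)
  cnt[cfg$controls, 1] <- cnt[cfg$controls, 1] + as.integer(ctrl_totals)
  est <- estimate_false_positive_rate(counts_to_sce(cnt))$fp_rate_per_cell

  n_cells <- nrow(sim$truth$cells)
  lambda <- 0.05 * n_cells / (length(cfg$genes) + length(cfg$controls))
  mc <- withr::with_seed(99, replicate(1000, max(rpois(20, lambda)) / n_cells))
  expect_lt(abs(est - mean(mc)), 3 * sd(mc))
})

test_that("active-gene filtering recovers the expressed set and is monotone", {
  sce <- embryo_pipeline(1)$sce
  totals <- Matrix::rowSums(SummarizedExperiment::assay(sce, "counts"))
  act_default <- filter_active_genes(sce)
  # genes with zero counts can never be active
  expect_false(any(totals[act_default] == 0))
  # controls are never active even at threshold 0
  act0 <- filter_active_genes(sce, min_total = 0)
  expect_false(any(grepl("nontargeting", act0)))
  expect_setequal(act0, names(totals)[totals > 0 &
                                        !grepl("nontargeting", names(totals))])
  # monotone: raising the threshold never adds a gene
  for (thr in c(0, 10, 100, 1000, 1e5)) {
    expect_true(all(filter_active_genes(sce, thr) %in% act0))
  }
  expect_true(all(filter_active_genes(sce, 100) %in%
                    filter_active_genes(sce, 10)))

  # exact ground-truth recovery in a background-free simulation
  cfg <- tiny_fate_map(background_rate_per_cell = 0, seed = 21)
  sim <- generate_embryo(cfg, seed = 21)
  act <- filter_active_genes(counts_to_sce(sim$truth$counts))
  expect_setequal(act, setdiff(cfg$genes, cfg$designations$silent))
})

test_that("pure-background data yields essentially no active genes", {
  for (seed in 1:5) {
    counts <- withr::with_seed(seed, matrix(
      rpois(30 * 400, 0.01), 30, 400,
      dimnames = list(c(sprintf("g%02d", 1:10),
                        sprintf("nontargeting_%02d", 1:20)), NULL)))
    act <- filter_active_genes(counts_to_sce(counts))
    expect_lte(length(act), 3)
  }
})

test_that("cell filtering flags low-count cells without deleting them", {
  counts <- matrix(0, 3, 4, dimnames = list(c("g1", "g2", "g3"), NULL))
  counts[, 2] <- c(5, 5, 0)   # exactly at threshold 10 -> retained
  counts[, 3] <- c(20, 5, 1)
  counts[, 4] <- c(2, 1, 0)
  sce <- counts_to_sce(counts)
  excl <- filter_cells(sce, active = c("g1", "g2", "g3"), min_cell_total = 10)
  expect_setequal(excl, c(1L, 4L))
  expect_equal(attr(excl, "flags"), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("detection-rate trends detect stability and injected decay", {
  cb <- build_codebook(sprintf("g%02d", 1:30), 0, seed = 1)
  # identical totals per gene: slope exactly 0, stable
  flat <- matrix(5, 30, 50, dimnames = list(cb$target, NULL))
  res <- detection_rate_by_cycle(counts_to_sce(flat), cb)
  expect_equal(res$slope, 0, tolerance = 1e-12)
  expect_true(res$stable)

  # 2%-per-cycle exponential decay: negative slope, flagged unstable
  cyc <- cb$cycle[match(rownames(flat), cb$target)]
  decayed <- flat * 0.98^(cyc - 1) * 100
  res2 <- detection_rate_by_cycle(counts_to_sce(decayed), cb)
  expect_lt(res2$slope, 0)
  expect_false(res2$stable)

  # a single cycle leaves the trend undefined
  cb1 <- build_codebook(c("a", "b", "c"), 0, seed = 1)
  one <- matrix(3, 3, 5, dimnames = list(c("a", "b", "c"), NULL))
  res3 <- detection_rate_by_cycle(counts_to_sce(one), cb1)
  expect_true(res3$trend_undefined)
})

test_that("nuclear volume stability reports the maximum relative drift", {
  v <- list(c(100, 110, 95), c(100, 110, 95))
  expect_equal(nuclear_volume_stability(v)$max_relative_drift, 0)
  v5 <- list(c(100, 110, 95), c(100, 110, 95) * 1.05)
  expect_equal(nuclear_volume_stability(v5)$max_relative_drift, 0.05)
  expect_equal(nuclear_volume_stability(v[1])$max_relative_drift, 0)
  # works directly on label volumes
  vol <- label_volume(array(c(1L, 1L, 0L, 2L), dim = c(4, 1, 1)), c(2, 2, 2))
  expect_equal(nuclear_volume_stability(list(vol))$median_volume_um3[[1]], 12)
})

test_that("the QC report aggregates and serializes", {
  px <- embryo_pipeline(1)
  rep <- qc_report(px$sce, px$sim$codebook)
  expect_s3_class(rep, "qc_report")
  expect_gte(rep$fp_rate_per_cell, 0)
  expect_true(all(rep$active_genes %in% rownames(px$sce)))
  path <- withr::local_tempfile(fileext = ".json")
  write_qc_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$fp_rate_per_cell, rep$fp_rate_per_cell)
  expect_output(print(rep), "fp rate")
})
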