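test_that("scaled gradient regression hits the analytic endpoints", {
  x <- seq(0, 40, length.out = 50)
  f <- fit_gradient(x, x)
  expect_equal(f$slope_k, 1)
  expect_equal(f$r2, 1)
  f2 <- fit_gradient(max(x) - x, x)
  expect_equal(f2$slope_k, -1)
  fc <- fit_gradient(rep(3, 50), x)
  expect_equal(fc$slope_k, 0)
  expect_true(fc$degenerate)
  expect_error(fit_gradient(x[1:10], x[1:10]), "required")
  # min-max scaling absorbs affine rescaling of the raw counts
  y <- withr::with_seed(1, rpois(50, 5 + x / 10))
  expect_equal(fit_gradient(7 * y + 2, x)$slope_k, fit_gradient(y, x)$slope_k)
})

test_that("injected log-linear gradients are recovered in sign and magnitude", {
  # generator-implied scaled slope: the expectation of the estimator under
  # the generating negative-binomial model, by parametric Monte-Carlo on the
  # same cells (min-max scaling of noisy counts makes the noiseless-profile
  # slope the wrong reference)
  implied_k <- function(base, slope, t, nb_size, reps = 40) {
    mean(vapply(seq_len(reps), function(i) {
      y <- stats::rnbinom(length(t), size = nb_size, mu = base * exp(slope * t))
      fit_gradient(y, t)$slope_k
    }, 0))
  }
  diffs <- c()
  for (seed in 1:5) {
    cfg <- tiny_fate_map(gradient_slope = 1.2, seed = seed)
    sim <- generate_embryo(cfg, seed = seed)
    g <- cfg$designations$gradient
    for (cl in c("C1", "C2", "C3")) {
      cells <- sim$truth$cells$cluster == cl
      t <- sim$truth$cells$dp_pos[cells]
      k_hat <- fit_gradient(as.numeric(sim$truth$counts[g, cells]), t)$slope_k
      k_imp <- withr::with_seed(1000 + seed,
                                implied_k(cfg$base_rates[g, cl], 1.2, t,
                                          cfg$nb_size))
      expect_gt(k_hat, 0)          # sign recovered in every fit
      diffs <- c(diffs, k_hat - k_imp)
    }
    if (seed == 5L) expect_lt(abs(mean(diffs)), 0.1)
    # descending direction recovers the negative sign too
    cfg2 <- tiny_fate_map(gradient_slope = -1.2, seed = seed)
    sim2 <- generate_embryo(cfg2, seed = seed)
    cells <- sim2$truth$cells$cluster == "C1"
    k2 <- fit_gradient(as.numeric(sim2$truth$counts[g, cells]),
                       sim2$truth$cells$dp_pos[cells])$slope_k
    expect_lt(k2, 0)
  }
})

test_that("the multi-gene gradient table and ranking are deterministic", {
  px <- embryo_pipeline(1)
  sim <- px$sim
  cents <- as.matrix(sim$truth$cells[, c("x_um", "y_um", "z_um")])
  cl <- sim$truth$cells$cluster
  ml <- fit_midline(cents, cl, c("C1", "C2", "C3"), orient_cluster = "C5")
  post <- colMeans(cents[cl == "C2", , drop = FALSE]) - ml$point
  ax <- transform_coordinates(cents, ml, post)
  fits <- fit_gradients(px$sce, ax, cl,
                        genes = sim$config$designations$gradient)
  expect_true(all(c("gene", "cluster", "axis", "slope_k") %in% names(fits)))
  expect_true(all(is.finite(fits$slope_k)))
  # the generator's dp-ascending gene comes out positive in its clusters
  g_up <- sim$config$designations$gradient[1]       # +1.5 in C1 and C5
  up <- fits[fits$gene == g_up & fits$axis == "dp" &
               fits$cluster %in% c("C1", "C5"), ]
  expect_true(all(up$slope_k > 0))

  # ranking: descending slope, ties lexicographic, input order irrelevant
  tb <- data.frame(gene = c("b", "a", "c"), slope_k = c(0.5, -0.5, 0.5))
  rk <- rank_genes_by_slope(tb)
  expect_equal(rk$gene, c("b", "c", "a"))
  expect_equal(rank_genes_by_slope(tb[c(3, 1, 2), ])$gene, rk$gene)
  ties <- data.frame(gene = c("z", "m", "a"), slope_k = 0)
  expect_equal(rank_genes_by_slope(ties)$gene, c("a", "m", "z"))
})

test_that("Spearman co-expression matches the explicit rank formula", {
  cnt <- withr::with_seed(5, matrix(rpois(8 * 3, 4), nrow = 3,
                                    dimnames = list(c("a", "b", "c"), NULL)))
  sce <- counts_to_sce(cnt)
  cm <- coexpression_matrix(sce, rep(1, 8), 1, genes = c("a", "b", "c"))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm$rho[i, j],
                 spearman_oracle(cnt[i, ], cnt[j, ]), tolerance = 1e-12)
  }
  expect_identical(cm$rho, t(cm$rho))
  expect_identical(diag(cm$rho), c(a = 1, b = 1, c = 1))
  # perfectly reversed ranks
  rev_cnt <- rbind(a = 1:8, b = 8:1)
  cm2 <- coexpression_matrix(counts_to_sce(rev_cnt), rep(1, 8), 1,
                             genes = c("a", "b"))
  expect_equal(cm2$rho["a", "b"], -1)
  # constant gene: masked zero, not an error
  const <- rbind(a = 1:8, b = rep(2, 8))
  cm3 <- coexpression_matrix(counts_to_sce(const), rep(1, 8), 1,
                             genes = c("a", "b"))
  expect_equal(cm3$rho["a", "b"], 0)
  expect_true(cm3$mask["a", "b"])
})

test_that("shared gradients without shared noise decouple slope from co-expression", {
  px <- embryo_pipeline(1)
  sim <- px$sim
  cl <- sim$truth$cells$cluster
  sce <- counts_to_sce(sim$truth$counts)
  pair_shared <- sim$config$designations$shared_gradient
  pair_factor <- sim$config$designations$coexpressed
  cm <- coexpression_matrix(sce, cl, "C1",
                            genes = c(pair_shared, pair_factor))
  # same dp gradient, independent noise: slope signs agree, |rho| stays low
  t <- sim$truth$cells$dp_pos[cl == "C1"]
  k1 <- fit_gradient(as.numeric(sim$truth$counts[pair_shared[1], cl == "C1"]), t)$slope_k
  k2 <- fit_gradient(as.numeric(sim$truth$counts[pair_shared[2], cl == "C1"]), t)$slope_k
  expect_equal(sign(k1), sign(k2))
  expect_lt(abs(cm$rho[pair_shared[1], pair_shared[2]]), 0.35)
  # a latent-factor pair co-expresses strongly
  expect_gt(cm$rho[pair_factor[1], pair_factor[2]], 0.4)
})

test_that("segment classification is exact on analytic profiles", {
  # one cell per segment position, perfectly linear counts
  n <- 9 * 20
  s <- rep(seq(0, 1, length.out = 9), each = 20)
  desc <- rep(seq(80, 0, length.out = 9), each = 20)
  flat <- rep(36, n)
  counts <- rbind(gd = desc, gf = flat)
  res <- classify_segments(counts_to_sce(counts), s)
  expect_equal(res$per_gene$slope_k[1], -1)
  expect_equal(res$per_gene$class[1], "descending")
  expect_equal(res$per_gene$slope_k[2], 0)
  expect_equal(res$per_gene$class[2], "flat")
  expect_error(classify_segments(counts_to_sce(counts), s, n_fit = 10), "n_fit")

  # an empty segment leaves a missing mean and flags short regressions
  s2 <- c(rep(0.05, 5), rep(0.5, 5), rep(0.95, 5))
  res2 <- classify_segments(counts_to_sce(matrix(3, 1, 15,
                                                 dimnames = list("g", NULL))),
                            s2, n_segments = 9, n_fit = 8)
  expect_true(any(is.na(res2$segment_means)))
  expect_true(res2$per_gene$flagged[1])
})

test_that("designated strong hippocampal gradients classify correctly over seeds", {
  for (seed in 1:5) {
    sim <- generate_hippocampus(seed = seed)
    sce <- counts_to_sce(sim$truth$counts)
    res <- classify_segments(sce, sim$truth$cells$arc_s)
    des <- sim$config$designations
    tab <- res$per_gene
    expect_true(all(tab$class[tab$gene %in% des$descending] == "descending"))
    expect_true(all(tab$class[tab$gene %in% des$ascending] == "ascending"))
  }
})
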