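test_that("RI aggregation reproduces the worked two-tree example", {
  # tree 1: g splits the root (fraction 1, IG .5), wAcc .8
  t1 <- manual_tree(feature = c(1L, NA, NA), threshold = c(0.5, NA, NA),
                    ig = c(0.5, 0, 0), count = c(10L, 5L, 5L),
                    parent = c(NA, 1L, 1L), depth = c(0L, 1L, 1L),
                    wacc = 0.8, feature_ids = c("g", "h"))
  # tree 2: g splits a child (fraction .4, IG .3), wAcc .6; root splits h
  t2 <- manual_tree(feature = c(2L, 1L, NA, NA, NA),
                    threshold = c(0.1, 0.2, NA, NA, NA),
                    ig = c(0.9, 0.3, 0, 0, 0), count = c(10L, 4L, 2L, 2L, 6L),
                    parent = c(NA, 1L, 2L, 2L, 1L),
                    depth = c(0L, 1L, 2L, 2L, 1L),
                    wacc = 0.6, feature_ids = c("g", "h"))
  ri <- compute_ri(list(t1, t2), mcfs_config(u = 1, v = 1))
  expect_equal(ri$ri[ri$feature == "g"], 0.8 * 0.5 * 1 + 0.6 * 0.3 * 0.4,
               tolerance = 1e-12)
  expect_equal(ri$ri[ri$feature == "g"], 0.472, tolerance = 1e-12)

  # v = 0 ignores the node fraction
  ri0 <- compute_ri(list(t1, t2), mcfs_config(u = 1, v = 0))
  expect_equal(ri0$ri[ri0$feature == "g"], 0.8 * 0.5 + 0.6 * 0.3,
               tolerance = 1e-12)
  expect_equal(ri0$ri[ri0$feature == "g"], 0.58, tolerance = 1e-12)

  # single tree, single unit-IG split, wAcc 1: RI 1 for g, 0 elsewhere
  t3 <- manual_tree(feature = c(1L, NA, NA), threshold = c(0, NA, NA),
                    ig = c(1, 0, 0), count = c(8L, 4L, 4L),
                    parent = c(NA, 1L, 1L), depth = c(0L, 1L, 1L),
                    wacc = 1, feature_ids = c("g", "h"))
  ri3 <- compute_ri(list(t3), mcfs_config())
  expect_equal(ri3$ri, c(1, 0))
  expect_equal(ri3$feature, c("g", "h"))
})

test_that("RI is additive over tree collections and rename-equivariant", {
  sim <- generate_dataset(synth_config(n_samples = 50, n_meth_features = 30,
                                       n_expr_features = 5, n_informative = 3,
                                       effect_size = 2, seed = 31))
  cfg <- mcfs_config(s = 40, m = 8, t = 2, min_split = 5)
  trees <- run_projections(sim$dataset, cfg, seed = 77)
  ids <- colnames(sim$dataset$values)
  ri_all <- compute_ri(trees, cfg, feature_ids = ids)
  ri_a <- compute_ri(trees[1:40], cfg, feature_ids = ids)
  ri_b <- compute_ri(trees[41:80], cfg, feature_ids = ids)
  merged <- setNames(ri_a$ri[match(ids, ri_a$feature)] +
                     ri_b$ri[match(ids, ri_b$feature)], ids)
  expect_equal(setNames(ri_all$ri[match(ids, ri_all$feature)], ids), merged,
               tolerance = 1e-12)

  # renaming features permutes RI labels, nothing else
  x <- sim$dataset$values
  y <- sim$dataset$class_label
  set.seed(5); f1 <- mcfs(x, y = y, cfg = cfg, cutoff = "none")
  colnames(x) <- paste0("renamed_", colnames(x))
  set.seed(5); f2 <- mcfs(x, y = y, cfg = cfg, cutoff = "none")
  expect_equal(paste0("renamed_", f1$ri$feature), f2$ri$feature)
  expect_equal(f1$ri$ri, f2$ri$ri)
})

test_that("streaming C++ accumulators equal the R reference on shared trees", {
  sim <- generate_dataset(synth_config(n_samples = 60, n_meth_features = 40,
                                       n_expr_features = 10, n_informative = 4,
                                       n_interacting_pairs = 1,
                                       effect_size = 1.5, seed = 17))
  cfg <- mcfs_config(s = 60, m = 10, t = 3, min_split = 5)
  set.seed(123)
  trees <- run_projections(sim$dataset, cfg)
  set.seed(123)
  fit <- mcfs(sim$dataset, cfg = cfg, cutoff = "none")

  ids <- colnames(sim$dataset$values)
  ri_ref <- compute_ri(trees, cfg, feature_ids = ids)
  expect_equal(coef(fit)[ri_ref$feature], setNames(ri_ref$ri, ri_ref$feature),
               tolerance = 1e-12)

  g_ref <- accumulate_id(trees, cfg)
  e_fit <- fit$id_graph$edges[order(fit$id_graph$edges$from,
                                    fit$id_graph$edges$to), ]
  rownames(e_fit) <- NULL
  expect_equal(e_fit$from, g_ref$edges$from)
  expect_equal(e_fit$to, g_ref$edges$to)
  expect_equal(e_fit$weight, g_ref$edges$weight, tolerance = 1e-12)
  expect_equal(e_fit$count, g_ref$edges$count)
})

test_that("projection bookkeeping: counts, determinism, m > p guard", {
  sim <- generate_dataset(synth_config(n_samples = 40, n_meth_features = 20,
                                       n_expr_features = 5, seed = 2))
  cfg <- mcfs_config(s = 10, m = 6, t = 5, min_split = 5)
  trees <- run_projections(sim$dataset, cfg, seed = 9)
  expect_length(trees, 50)

  # one projection over all features, fixed seed: identical twice
  cfg1 <- mcfs_config(s = 1, m = 25, t = 1, min_split = 5)
  tr_a <- run_projections(sim$dataset, cfg1, seed = 4)[[1]]
  tr_b <- run_projections(sim$dataset, cfg1, seed = 4)[[1]]
  expect_identical(tr_a$feature, tr_b$feature)
  expect_identical(tr_a$threshold, tr_b$threshold)
  expect_identical(tr_a$wacc, tr_b$wacc)

  expect_error(mcfs(sim$dataset, cfg = mcfs_config(s = 2, m = 100, t = 1)),
               "exceeds")
})

test_that("held-out weighted accuracy is centred at 1/2 under the null", {
  set.seed(61)
  x <- matrix(rnorm(100 * 50), 100, 50)
  colnames(x) <- paste0("F", 1:50)
  y <- rep(0:1, each = 50)
  fit <- mcfs(x, y = y, cfg = mcfs_config(s = 100, m = 10, t = 5,
                                          min_split = 5),
              cutoff = "none", seed = 3)
  expect_length(fit$wacc, 500)
  expect_gt(mean(fit$wacc), 0.45)
  expect_lt(mean(fit$wacc), 0.55)
})

test_that("monotone transforms leave split partitions and rankings unchanged", {
  # splits are rank-based, so a strictly monotone transform preserves every
  # tree structure (features, gains, node counts). Held-out evaluation is
  # the one non-rank-based ingredient: midpoint thresholds are not
  # equivariant, so a test sample lying between midpoint(a, b) and
  # midpoint(g(a), g(b)) may switch sides. RI is therefore exactly
  # invariant with u = 0 (no wAcc weighting), and structurally invariant
  # at the default u.
  sim <- generate_dataset(synth_config(n_samples = 50, n_meth_features = 25,
                                       n_expr_features = 5, n_informative = 3,
                                       effect_size = 2, seed = 44))
  x <- sim$dataset$values
  y <- sim$dataset$class_label
  # x^3 is strictly monotone on the non-negative values of both feature kinds
  cfg <- mcfs_config(s = 30, m = 8, t = 2, min_split = 5)
  set.seed(10); tr1 <- run_projections(x, cfg, y = y)
  set.seed(10); tr2 <- run_projections(x^3, cfg, y = y)
  for (i in seq(1, length(tr1), by = 7)) {
    expect_identical(tr1[[i]]$feature, tr2[[i]]$feature)
    expect_identical(tr1[[i]]$count, tr2[[i]]$count)
    expect_equal(tr1[[i]]$ig, tr2[[i]]$ig, tolerance = 1e-12)
  }

  cfg0 <- mcfs_config(s = 30, m = 8, t = 2, min_split = 5, u = 0)
  set.seed(10); f1 <- mcfs(x, y = y, cfg = cfg0, cutoff = "none")
  set.seed(10); f2 <- mcfs(x^3, y = y, cfg = cfg0, cutoff = "none")
  expect_equal(f1$ri$feature, f2$ri$feature)
  expect_equal(f1$ri$ri, f2$ri$ri, tolerance = 1e-12)
})

test_that("the permutation cutoff separates planted signal from noise", {
  # a planted strong feature is flagged in nearly every repeat
  flagged <- 0L
  for (rep_i in 1:10) {
    sim <- generate_dataset(synth_config(n_samples = 200,
                                         n_meth_features = 49,
                                         n_expr_features = 1,
                                         n_informative = 1, effect_size = 2,
                                         seed = 500 + rep_i))
    fit <- mcfs(sim$dataset,
                cfg = mcfs_config(s = 60, m = 10, t = 3),
                cutoff = "permutation", n_perm = 8, seed = 600 + rep_i)
    flagged <- flagged +
      (sim$truth$informative_ids %in% significant_features(fit))
  }
  expect_gte(flagged, 9)

  # confidence -> 1 sends the cutoff to infinity
  sim <- generate_dataset(synth_config(n_samples = 60, n_meth_features = 30,
                                       n_expr_features = 5, seed = 71))
  fit1 <- mcfs(sim$dataset, cfg = mcfs_config(s = 20, m = 8, t = 2),
               cutoff = "permutation", n_perm = 3, confidence = 1, seed = 8)
  expect_equal(fit1$cutoff$cutoff_value, Inf)
  expect_equal(sum(fit1$ri$significant), 0)
})
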