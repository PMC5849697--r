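test_that("plug-in MI matches the closed forms", {
  # perfectly aligned 2x2 table: 1 bit; uniform table: 0 bits
  x <- rep(c(0, 1), each = 4)
  expect_equal(mutual_information(x, x, n_bins = 2), 1)
  y_unif <- c(0, 0, 1, 1, 0, 0, 1, 1)
  expect_equal(mutual_information(x, y_unif, n_bins = 2), 0)

  # binary x identical to balanced y: H(y) = 1 bit
  expect_equal(mutual_information(rep(0:1, 50), rep(0:1, 50)), 1)

  # constant x carries no information
  expect_equal(mutual_information(rep(1, 20), rep(0:1, 10)), 0)

  # independence: MI shrinks toward 0 with n
  set.seed(2)
  mi_large <- mutual_information(rnorm(20000), rep(0:1, 10000))
  expect_lt(mi_large, 0.01)

  # rank-based binning: invariant under monotone transforms
  set.seed(3)
  x <- rexp(200)
  y <- rep(0:1, 100)
  expect_equal(mutual_information(x, y), mutual_information(log(x), y))

  expect_error(mutual_information(c(1, 2, 3), c(0, 1, 0)), "at least 4")
})

test_that("MI permutation significance separates signal from noise", {
  sim <- generate_dataset(synth_config(n_samples = 200, n_meth_features = 20,
                                       n_expr_features = 5, n_informative = 2,
                                       effect_size = 2, seed = 9))
  res <- withr::with_seed(1,
    mi_significance(sim$dataset, n_perm = 1000))
  planted <- res[res$feature %in% sim$truth$informative_ids, ]
  expect_true(all(planted$p_value < 0.01))
  expect_true(all(planted$significant))

  # plus-one convention: p is never 0 and never above 1
  expect_true(all(res$p_value >= 1 / 1001 & res$p_value <= 1))

  # null rejection rate near alpha without correction
  set.seed(11)
  x <- matrix(rnorm(150 * 40), 150, 40, dimnames = list(NULL, paste0("F", 1:40)))
  y <- rep(0:1, length.out = 150)
  null_res <- mi_significance(x, y = y, n_perm = 200)
  expect_lt(mean(null_res$p_value < 0.05), 0.15)
  expect_equal(sum(null_res$significant), 0) # Bonferroni holds the family
})

test_that("interaction information has the textbook signs and symmetry", {
  # XOR: pure synergy, +1 bit
  g <- expand.grid(x = 0:1, z = 0:1)[rep(1:4, 25), ]
  y <- as.integer(xor(g$x, g$z))
  ii_xor <- interaction_information(g$x, g$z, y, n_bins = 2)
  expect_equal(ii_xor$ii, 1)

  # full redundancy: z a copy of x, y = x: -1 bit
  x <- rep(0:1, 50)
  ii_red <- interaction_information(x, x, x, n_bins = 2)
  expect_equal(ii_red$ii, -1)

  # independent z leaves the x-y dependence untouched
  set.seed(21)
  x2 <- rnorm(4000); y2 <- as.integer(x2 > 0); z2 <- rnorm(4000)
  expect_lt(abs(interaction_information(x2, z2, y2)$ii), 0.02)

  # chain identity I(x;y|z) - I(x;y) = I(x;z|y) - I(x;z) on random triples
  set.seed(31)
  for (i in 1:20) {
    dx <- sample(1:3, 60, TRUE); dz <- sample(1:2, 60, TRUE)
    dy <- sample(0:1, 60, TRUE)
    a <- interaction_information(dx, dz, dy, n_bins = 3)$ii
    b <- interaction_information(dx, dy, dz, n_bins = 3)$ii
    expect_equal(a, b, tolerance = 1e-12)
  }

  # permutation p: synergy detected, independence not
  set.seed(41)
  p_xor <- interaction_information(g$x, g$z, y, n_bins = 2, n_perm = 199)$p_value
  expect_lt(p_xor, 0.01)
})

test_that("Kruskal-Wallis H matches the rank formula and rank-sum identity", {
  # direct rank computation for {1,2,3} vs {4,5,6}:
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2
  H_hand <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1, dimnames = list(NULL, "f"))
  res <- kw_bonferroni(x, y = c(0, 0, 0, 1, 1, 1))
  expect_equal(res$H, H_hand, tolerance = 1e-12)
  expect_equal(res$H, 3.857142857, tolerance = 1e-8)

  # identical groups: H = 0, p = 1
  res0 <- kw_bonferroni(matrix(rep(1, 8), ncol = 1, dimnames = list(NULL, "f")),
                        y = rep(0:1, 4))
  expect_equal(res0$H, 0)
  expect_equal(res0$p_value, 1)

  # two-group KW equals the squared standardized rank-sum statistic
  set.seed(77)
  for (i in 1:100) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1)
    v <- sample(1000, n1 + n2) # tie-free
    y <- rep(0:1, c(n1, n2))
    H <- kw_bonferroni(matrix(v, ncol = 1, dimnames = list(NULL, "f")),
                       y = y)$H
    U <- unname(wilcox.test(v[y == 0], v[y == 1], exact = FALSE,
                            correct = FALSE)$statistic)
    N <- n1 + n2
    z2 <- (U - n1 * n2 / 2)^2 / (n1 * n2 * (N + 1) / 12)
    expect_equal(H, z2, tolerance = 1e-10)
  }

  # Bonferroni is multiplication capped at 1
  expect_equal(p.adjust(rep(0.001, 1)[1] , "bonferroni", n = 65), 0.065)
})

test_that("correlation matrices carry extras and flag degenerate columns", {
  ds <- tiny_dataset(n = 30)
  cm <- correlation_matrix(ds, method = "pearson")
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_true(all(c("age", "DtD") %in% colnames(cm)))
  expect_true(all(abs(cm) <= 1 + 1e-12))

  # anti-correlated pair
  ds$values[, 2] <- 1 - ds$values[, 1]
  cm2 <- correlation_matrix(ds, features = colnames(ds$values)[1:2],
                            extras = character(0))
  expect_equal(cm2[1, 2], -1)

  # hand-checked Spearman rho on a 5-point set
  sx <- c(1, 2, 3, 4, 5); sy <- c(2, 1, 5, 4, 3)
  d2 <- sum((rank(sx) - rank(sy))^2)
  rho_hand <- 1 - 6 * d2 / (5 * (25 - 1))
  m <- matrix(c(sx, sy), 5, 2, dimnames = list(paste0("s", 1:5), c("a", "b")))
  dsp <- omics_dataset(m, rep("expression", 2), survival_days = 1:5)
  cmsp <- correlation_matrix(dsp, extras = character(0), method = "spearman")
  expect_equal(cmsp["a", "b"], rho_hand)
  expect_equal(cmsp["a", "b"], 0.5)

  ds$values[, 3] <- 0.5
  expect_warning(correlation_matrix(ds), "zero-variance")
})

test_that("methylation-expression pairing reports per-gene correlations", {
  sim <- generate_dataset(synth_config(n_samples = 80, n_meth_features = 10,
                                       n_expr_features = 10, seed = 12))
  ds <- sim$dataset
  # make one probe strongly anti-correlated with its gene
  ds$values[, "GENE0001"] <- (1 - ds$values[, "cg000001"]) * 100
  pg <- data.frame(probe_id = c("cg000001", "cg000002", "cg_missing"),
                   gene_id = c("GENE0001", "GENE0002", "GENE0001"))
  res <- meth_expr_correlation(ds, pg)
  expect_equal(nrow(res), 2) # unknown probe skipped
  expect_equal(res$probe_id[1], "cg000001")
  expect_equal(res$rho[1], -1)
})
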