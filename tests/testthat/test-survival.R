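test_that("histogram scan flags a drop where the density falls away", {
  # uniform day distribution: drops stay within sampling noise of zero,
  # judged relative to the mean bin occupancy
  set.seed(1)
  d_unif <- sample(1:1000, 20000, TRUE)
  scan_u <- survival_histogram_scan(d_unif, bin_width = 50,
                                    scan_range = c(100, 900))
  expect_lt(max(abs(scan_u$candidates$drop)),
            0.08 * mean(scan_u$histogram$count))

  # power-law days: drops positive and shrinking with the threshold
  d_pl <- generate_survival(5000, alpha = 1.5, max_days = 4084, seed = 2)
  scan_p <- survival_histogram_scan(d_pl, bin_width = 50,
                                    scan_range = c(100, 1000))
  cand <- scan_p$candidates
  expect_true(all(cand$drop > 0))
  expect_lt(cor(cand$threshold, cand$drop, method = "spearman"), 0)

  expect_error(survival_histogram_scan(c(100, 200), scan_range = c(500, 900)),
               "outside")
  expect_error(survival_histogram_scan(c(-1, 10)), "positive")
})

test_that("beta-value strata follow the closed-interval convention", {
  rule <- strata_rule(0.96, 0.85)
  expect_equal(as.character(stratify_by_beta(c(0.97, 0.80, 0.96, 0.85, 0.90),
                                             rule)),
               c("High", "Low", "Medium", "Medium", "Medium"))
  expect_error(stratify_by_beta(c(1.2), rule), "0, 1")
  expect_error(strata_rule(0.8, 0.9), "exceed")
})

test_that("product-limit estimates match hand-computed cases", {
  # three deaths at distinct times: S = 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # tied deaths pooled: d = 2 of n = 3 at t = 2
  km2 <- km_estimate(c(2, 2, 4))
  expect_equal(km2$surv[km2$time == 2], 1 / 3)

  # no events: flat at 1
  km3 <- km_estimate(c(5, 6, 7), events = c(0, 0, 0))
  expect_true(all(km3$surv == 1))

  # all-event KM equals 1 - ECDF at the event times
  set.seed(9)
  d <- sample(1:500, 40)
  km4 <- km_estimate(d)
  expect_equal(km4$surv, 1 - ecdf(d)(km4$time))

  # survival probabilities are monotone non-increasing within a stratum
  strata <- rep(c("A", "B"), each = 20)
  km5 <- km_estimate(d, strata = strata)
  for (s in c("A", "B"))
    expect_true(all(diff(km5$surv[km5$stratum == s]) <= 1e-12))
})

test_that("log-rank matches a brute-force observed-minus-expected oracle", {
  # identical groups: no signal
  res0 <- log_rank_test(c(1, 2, 3, 1, 2, 3), group = rep(c("a", "b"), each = 3))
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)

  # hand case {1,2,3} vs {4,5,6}: accumulate O-E and hypergeometric
  # variance over the six event times
  d <- c(1, 2, 3, 4, 5, 6); grp <- rep(c("a", "b"), each = 3)
  oe <- 0; vv <- 0
  for (tt in sort(d)) {
    at_risk <- d >= tt
    n_tot <- sum(at_risk); n_a <- sum(at_risk & grp == "a")
    d_tot <- sum(d == tt); d_a <- sum(d == tt & grp == "a")
    oe <- oe + d_a - d_tot * n_a / n_tot
    if (n_tot > 1)
      vv <- vv + d_tot * (n_a / n_tot) * (1 - n_a / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  chisq_hand <- oe^2 / vv
  res <- log_rank_test(d, group = grp)
  expect_equal(res$chisq, chisq_hand, tolerance = 1e-10)
  expect_equal(res$df, 1L)

  # invariance under monotone re-timing of the event days
  res2 <- log_rank_test(d^2 + 10, group = grp)
  expect_equal(res2$chisq, res$chisq, tolerance = 1e-12)

  # one subject per group still computes
  res1 <- log_rank_test(c(3, 9), group = c("a", "b"))
  expect_true(is.finite(res1$chisq))

  # no events at all: p = 1 with a warning
  expect_warning(resn <- log_rank_test(c(1, 2), events = c(0, 0),
                                       group = c("a", "b")),
                 "no events")
  expect_equal(resn$p_value, 1)
})

test_that("the per-probe analysis stratifies, estimates and tests", {
  set.seed(5)
  n <- 90
  beta <- c(runif(30, 0.97, 1), runif(30, 0.5, 0.84), runif(30, 0.86, 0.96))
  days <- c(rpois(30, 600), rpois(30, 200), rpois(30, 400)) + 1
  m <- matrix(beta, ncol = 1, dimnames = list(paste0("S", 1:n), "cgTOP"))
  ds <- omics_dataset(m, "methylation", survival_days = days)
  res <- km_probe_analysis(ds, "cgTOP")
  expect_equal(as.vector(table(res$strata)), c(30, 30, 30))
  expect_lt(res$logrank$p_value, 0.001) # High outlives Low by construction
  expect_setequal(unique(res$curves$stratum), c("Low", "Medium", "High"))
  expect_error(km_probe_analysis(ds, "cgNOPE"), "unknown probe")
})
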