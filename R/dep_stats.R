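#' Equal-frequency discretization
#'
#' Cuts a numeric vector at its empirical quantiles into (at most)
#' `n_bins` bins. Rank-based, so any strictly monotone transform of `x`
#' yields the identical binning — this is what keeps the plug-in MI
#' estimator nonparametric. Vectors with fewer distinct values than bins
#' (including factors passed through unchanged) keep their natural levels.
#'
#' @param x numeric vector or factor.
#' @param n_bins target number of bins (default 5).
#' @return integer factor of bin memberships.
#' @export
discretize_ef <- function(x, n_bins = 5L) {
  if (is.factor(x) || is.character(x) || is.logical(x)) return(as.factor(x))
  if (length(unique(x)) <= 1L) return(factor(rep(1L, length(x))))
  if (length(unique(x)) <= n_bins) return(as.factor(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE) |> factor()
}

mi_from_table <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
}

#' Plug-in mutual information with the class (bits)
#'
#' `x` is discretized by equal-frequency binning and MI with `y` computed
#' from the empirical joint: `sum p(x,y) log2[p(x,y) / (p(x) p(y))]`.
#' Non-negative; bounded by both `H(y)` and `log2(n_bins)`. A constant `x`
#' gives MI = 0.
#'
#' @param x numeric feature vector (length >= 4).
#' @param y class vector.
#' @param n_bins bins for `x` (default 5).
#' @return MI in bits.
#' @export
mutual_information <- function(x, y, n_bins = 5L) {
  if (length(x) < 4) stop("need at least 4 observations")
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  mi_from_table(table(discretize_ef(x, n_bins), as.factor(y)))
}

#' Permutation significance of per-feature MI
#'
#' For each feature, a permutation p-value from `n_perm` class-label
#' shuffles using the plus-one convention `(b + 1) / (B + 1)`, with
#' Bonferroni correction over the tested features. The feature
#' discretization is fixed under label permutation, so it is computed once.
#'
#' @param ds an [omics_dataset()] with classes assigned, or a matrix with
#'   `y` supplied.
#' @param features feature ids (or column indices) to test; default all.
#' @param n_perm number of permutations (>= 100).
#' @param alpha family-wise significance level (default 0.05).
#' @param n_bins bins for the features.
#' @param y class vector when `ds` is a matrix.
#' @return data.frame `feature`, `mi`, `p_value`, `p_bonferroni`,
#'   `significant`.
#' @export
mi_significance <- function(ds, features = NULL, n_perm = 1000L, alpha = 0.05,
                            n_bins = 5L, y = NULL) {
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  xy <- resolve_xy(ds, y)
  if (is.null(features)) features <- colnames(xy$x)
  x <- xy$x[, features, drop = FALSE]
  yf <- as.factor(xy$y)
  disc <- lapply(seq_len(ncol(x)), function(j) discretize_ef(x[, j], n_bins))
  obs <- vapply(disc, function(d) mi_from_table(table(d, yf)), 0)
  exceed <- integer(ncol(x))
  for (b in seq_len(n_perm)) {
    yp <- sample(yf)
    perm <- vapply(disc, function(d) mi_from_table(table(d, yp)), 0)
    exceed <- exceed + (perm >= obs)
  }
  p <- (exceed + 1) / (n_perm + 1)
  p_bonf <- pmin(1, p * ncol(x))
  data.frame(feature = colnames(x), mi = obs, p_value = p,
             p_bonferroni = p_bonf, significant = p_bonf <= alpha,
             stringsAsFactors = FALSE)
}

cond_mi <- function(dx, dy, dz) {
  # I(x; y | z) = sum_z p(z) I(x; y | Z = z), plug-in
  n <- length(dz)
  total <- 0
  for (lev in levels(dz)) {
    sel <- dz == lev
    if (!any(sel)) next
    total <- total + sum(sel) / n * mi_from_table(table(dx[sel], dy[sel]))
  }
  total
}

#' Interaction information of (feature, covariate, class)
#'
#' `II = I(x; y | z) - I(x; y)` on the discretized triple: positive values
#' indicate synergy (the covariate z creates dependence between x and the
#' class, as in an XOR), negative values redundancy (z already carries the
#' x-class dependence). Used to check whether age or gender modulates a
#' feature-survival dependence. The permutation null shuffles `z` within
#' each class, which preserves I(x; y) and breaks only the three-way
#' interaction.
#'
#' @param x numeric feature vector.
#' @param z covariate (numeric, discretized like `x`, or categorical).
#' @param y class vector.
#' @param n_bins equal-frequency bins for numeric inputs.
#' @param n_perm permutations for the p-value (0 skips it).
#' @return list with `ii` (bits) and `p_value` (NA when `n_perm = 0`).
#' @export
interaction_information <- function(x, z, y, n_bins = 5L, n_perm = 0L) {
  dx <- discretize_ef(x, n_bins)
  dz <- discretize_ef(z, n_bins)
  dy <- as.factor(y)
  ii_obs <- cond_mi(dx, dy, dz) - mi_from_table(table(dx, dy))
  p <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      zp <- dz
      for (lev in levels(dy)) {
        sel <- which(dy == lev)
        zp[sel] <- dz[sample(sel)]
      }
      ii_b <- cond_mi(dx, dy, zp) - mi_from_table(table(dx, dy))
      if (abs(ii_b) >= abs(ii_obs)) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  list(ii = ii_obs, p_value = p)
}

#' Kruskal-Wallis tests with Bonferroni correction
#'
#' Rank-based H statistic (tie-corrected, chi-square approximation with
#' df = number of classes - 1) per feature, with the Bonferroni multiplier
#' equal to the number of tested features. With two classes this is
#' equivalent to the Wilcoxon rank-sum test.
#'
#' @param ds an [omics_dataset()] with classes assigned, or a matrix with
#'   `y` supplied.
#' @param features feature ids to test; default all.
#' @param y class vector when `ds` is a matrix.
#' @return data.frame `feature`, `H`, `p_value`, `p_bonferroni`.
#' @export
kw_bonferroni <- function(ds, features = NULL, y = NULL) {
  xy <- resolve_xy(ds, y)
  if (is.null(features)) features <- colnames(xy$x)
  x <- xy$x[, features, drop = FALSE]
  yf <- as.factor(xy$y)
  if (min(table(yf)) < 3) stop("need >= 3 samples per class")
  res <- apply(x, 2, function(col) {
    if (length(unique(col)) == 1L) return(c(H = 0, p = 1))
    kt <- stats::kruskal.test(col, yf)
    c(H = unname(kt$statistic), p = kt$p.value)
  })
  data.frame(feature = colnames(x), H = res["H", ], p_value = res["p", ],
             p_bonferroni = stats::p.adjust(res["p", ], method = "bonferroni"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation matrix of selected features plus clinical extras
#'
#' Pearson or Spearman correlation over the chosen features with optional
#' extra columns appended (by default `age` from the covariates and the
#' raw days-to-death, `DtD`). Zero-variance columns yield NA entries and a
#' warning.
#'
#' @param ds an [omics_dataset()].
#' @param features feature ids; default all.
#' @param extras character subset of `c("age", "DtD")` to append.
#' @param method `"pearson"` or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ds, features = NULL,
                               extras = c("age", "DtD"),
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "omics_dataset"))
  if (nrow(ds$values) < 3) stop("need at least 3 samples")
  if (is.null(features)) features <- colnames(ds$values)
  m <- ds$values[, features, drop = FALSE]
  if ("age" %in% extras && !is.null(ds$covariates) &&
      "age" %in% colnames(ds$covariates))
    m <- cbind(m, age = as.numeric(ds$covariates$age))
  if ("DtD" %in% extras)
    m <- cbind(m, DtD = as.numeric(ds$survival_days))
  zv <- apply(m, 2, stats::var) == 0
  if (any(zv))
    warning("zero-variance column(s) give undefined correlations: ",
            paste(colnames(m)[zv], collapse = ", "))
  suppressWarnings(stats::cor(m, method = method))
}

#' Methylation-expression correlation of paired features
#'
#' Spearman (default) correlation between each methylation probe and the
#' expression of its assigned gene, given a probe-to-gene map.
#'
#' @param ds an [omics_dataset()].
#' @param probe_gene data.frame with columns `probe_id`, `gene_id`.
#' @param method correlation method (default `"spearman"`).
#' @return data.frame `probe_id`, `gene_id`, `rho`, sorted by |rho|
#'   descending; pairs whose members are absent from the dataset are
#'   skipped.
#' @export
meth_expr_correlation <- function(ds, probe_gene,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "omics_dataset"),
            all(c("probe_id", "gene_id") %in% colnames(probe_gene)))
  keep <- probe_gene$probe_id %in% colnames(ds$values) &
          probe_gene$gene_id %in% colnames(ds$values)
  pg <- probe_gene[keep, , drop = FALSE]
  rho <- mapply(function(p, g)
    suppressWarnings(stats::cor(ds$values[, p], ds$values[, g],
                                method = method)),
    pg$probe_id, pg$gene_id)
  out <- data.frame(probe_id = pg$probe_id, gene_id = pg$gene_id,
                    rho = unname(rho), stringsAsFactors = FALSE)
  out[order(-abs(out$rho)), , drop = FALSE]
}
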