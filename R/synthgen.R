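#' Configuration for the synthetic TCGA-like generator
#'
#' Describes a synthetic glioma-style cohort: methylation beta-values from
#' Beta distributions, heavy-right-tailed (log-normal) expression, a
#' power-law-like survival-time density dichotomized at a day threshold,
#' planted marginally informative features, planted XOR-interacting feature
#' pairs (jointly informative, marginally silent), correlated nuisance
#' blocks, and age/gender/grade covariates independent of the class.
#'
#' Defaults mirror the real cohort the pipeline targets: an 88-patient
#' all-deceased glioma training set with 38 short-term (<= 400 days) and 50
#' long-term survivors, survival days spanning 7 to 4084.
#'
#' @param n_samples number of patients (default 88).
#' @param n_meth_features,n_expr_features feature counts per block.
#' @param n_informative planted marginal signals (split between blocks,
#'   methylation first).
#' @param effect_size class shift of informative features: logit-scale mean
#'   beta-value shift and natural-log fold change for expression.
#' @param n_interacting_pairs planted XOR pairs (methylation block).
#' @param block_corr within-block latent correlation of nuisance features;
#'   0 disables blocks.
#' @param block_size features per correlated nuisance block.
#' @param survival_alpha exponent of the power-law survival density
#'   (must exceed 1); density proportional to days^(-alpha).
#' @param min_days,max_days survival-day support (defaults 7 and 4084).
#' @param threshold_days class dichotomy threshold (default 400).
#' @param short_frac fraction of SHORT-class samples (default 38/88).
#' @param label_noise XOR pair label-noise rate (default 0.1).
#' @param beta_precision Beta precision kappa: beta-values are drawn from
#'   Beta(mu * kappa, (1 - mu) * kappa), giving the narrow, high
#'   beta-distributions seen at prognostic CpGs.
#' @param seed integer seed; one global seed drives a named sub-stream per
#'   block so that enlarging one block does not perturb another.
#' @export
synth_config <- function(n_samples = 88, n_meth_features = 800,
                         n_expr_features = 200, n_informative = 10,
                         effect_size = 1.5, n_interacting_pairs = 0,
                         block_corr = 0, block_size = 10,
                         survival_alpha = 1.5, min_days = 7, max_days = 4084,
                         threshold_days = 400, short_frac = 38 / 88,
                         label_noise = 0.1, beta_precision = 50,
                         seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_meth_features = as.integer(n_meth_features),
              n_expr_features = as.integer(n_expr_features),
              n_informative = as.integer(n_informative),
              effect_size = effect_size,
              n_interacting_pairs = as.integer(n_interacting_pairs),
              block_corr = block_corr, block_size = as.integer(block_size),
              survival_alpha = survival_alpha,
              min_days = as.integer(min_days), max_days = as.integer(max_days),
              threshold_days = as.integer(threshold_days),
              short_frac = short_frac, label_noise = label_noise,
              beta_precision = beta_precision, seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_samples, n_meth_features, n_expr_features) < 1))
      stop("sample and feature counts must be positive")
    if (n_informative < 0 || n_interacting_pairs < 0)
      stop("planted feature counts must be non-negative")
    if (n_informative + 2L * n_interacting_pairs >
        n_meth_features + n_expr_features)
      stop("more planted features than total features")
    if (2L * n_interacting_pairs > n_meth_features)
      stop("XOR pairs are planted in the methylation block; too many pairs")
    if (survival_alpha <= 1) stop("`survival_alpha` must exceed 1")
    if (block_corr < 0 || block_corr >= 1) stop("`block_corr` must be in [0,1)")
  })
  class(cfg) <- "synth_config"
  cfg
}

#' Draw survival times from a discrete power-law density
#'
#' Days are drawn from `min_days:max_days` with probability proportional to
#' `d^(-alpha)` — the roughly power-function-shaped density of glioma
#' days-to-death. All draws are events (deceased).
#'
#' @param n number of draws.
#' @param alpha exponent (> 1).
#' @param max_days support cap (default 4084, the longest observed
#'   survival in the target cohort).
#' @param min_days support floor (default 1).
#' @param seed optional integer seed.
#' @return integer vector of days.
#' @export
generate_survival <- function(n, alpha, max_days = 4084L, min_days = 1L,
                              seed = NULL) {
  if (alpha <= 1) stop("`alpha` must exceed 1 (non-normalizable otherwise)")
  if (max_days < 1 || min_days < 1 || min_days > max_days)
    stop("need 1 <= min_days <= max_days")
  if (!is.null(seed)) set.seed(seed)
  support <- seq.int(min_days, max_days)
  sample(support, n, replace = TRUE, prob = support^(-alpha))
}

# power-law days truncated to one side of the threshold
rsurv_truncated <- function(n, alpha, min_days, max_days, lo, hi) {
  support <- seq.int(max(min_days, lo), min(max_days, hi))
  if (!length(support)) stop("empty survival support after truncation")
  if (length(support) == 1L) return(rep(support, n))
  sample(support, n, replace = TRUE, prob = support^(-alpha))
}

#' Generate a synthetic omics dataset with known ground truth
#'
#' The class label is drawn first (SHORT with probability `short_frac`);
#' survival days are then drawn from the power-law density truncated to the
#' class's side of the threshold, so the class is a deterministic function
#' of days and threshold while the day density keeps its power-law shape.
#' Informative methylation features get a class-dependent Beta mean
#' (logit-scale shift `effect_size`); informative expression features a
#' log-scale mean shift. XOR pairs are built by dichotomizing two latent
#' signals so that class = parity of the pair (with `label_noise` errors):
#' each member is marginally independent of the class, the pair jointly
#' predictive. All values are produced through link functions (no
#' clipping), so beta-values stay in \[0, 1\] and expression non-negative.
#'
#' @param cfg a [synth_config()].
#' @return list with `dataset` (an [omics_dataset()] with classes assigned),
#'   `truth` (a `synthetic_truth`: planted ids, pairs, effect sizes, class),
#'   and `probes` (synthetic probe coordinates for the methylation
#'   features, usable by [make_regions()]).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  stream <- stats::setNames(sample.int(.Machine$integer.max - 1L, 6L),
                            c("class", "survival", "meth", "expr",
                              "covariates", "coords"))
  n <- cfg$n_samples
  p_meth <- cfg$n_meth_features
  p_expr <- cfg$n_expr_features

  ## class + survival ---------------------------------------------------
  set.seed(stream[["class"]])
  cls <- stats::rbinom(n, 1L, 1 - cfg$short_frac) # 0 = SHORT, 1 = LONG
  # degenerate draws would break stratified tree splits downstream
  if (sum(cls == 0L) < 2L) cls[seq_len(2L)] <- 0L
  if (sum(cls == 1L) < 2L) cls[n - seq_len(2L) + 1L] <- 1L
  set.seed(stream[["survival"]])
  days <- integer(n)
  days[cls == 0L] <- rsurv_truncated(sum(cls == 0L), cfg$survival_alpha,
                                     cfg$min_days, cfg$max_days,
                                     1L, cfg$threshold_days)
  days[cls == 1L] <- rsurv_truncated(sum(cls == 1L), cfg$survival_alpha,
                                     cfg$min_days, cfg$max_days,
                                     cfg$threshold_days + 1L, cfg$max_days)

  ## planted feature layout ---------------------------------------------
  n_inf_meth <- min(ceiling(cfg$n_informative / 2), p_meth - 2L * cfg$n_interacting_pairs)
  n_inf_expr <- cfg$n_informative - n_inf_meth
  if (n_inf_expr > p_expr) stop("expression block too small for planted features")
  inf_meth <- seq_len(n_inf_meth)
  pair_cols <- if (cfg$n_interacting_pairs > 0)
    matrix(n_inf_meth + seq_len(2L * cfg$n_interacting_pairs),
           ncol = 2, byrow = TRUE) else matrix(integer(0), ncol = 2)
  inf_expr <- seq_len(n_inf_expr)

  ## methylation block ---------------------------------------------------
  set.seed(stream[["meth"]])
  kappa <- cfg$beta_precision
  base_mu <- stats::runif(p_meth, 0.3, 0.7)
  logit_mu <- matrix(stats::qlogis(base_mu), n, p_meth, byrow = TRUE)
  # class shift on the logit scale for informative CpGs
  if (n_inf_meth > 0) {
    shift <- outer(cls - 0.5, rep(cfg$effect_size, n_inf_meth))
    logit_mu[, inf_meth] <- logit_mu[, inf_meth] + shift
  }
  # correlated nuisance blocks via a shared latent factor
  if (cfg$block_corr > 0) {
    nuisance <- setdiff(seq_len(p_meth), c(inf_meth, as.vector(pair_cols)))
    blocks <- split(nuisance, ceiling(seq_along(nuisance) / cfg$block_size))
    r <- cfg$block_corr
    for (b in blocks) {
      z <- stats::rnorm(n)
      e <- matrix(stats::rnorm(n * length(b)), n, length(b))
      logit_mu[, b] <- logit_mu[, b] + 1.5 * (sqrt(r) * z + sqrt(1 - r) * e)
    }
  } else {
    nuisance <- setdiff(seq_len(p_meth), c(inf_meth, as.vector(pair_cols)))
    logit_mu[, nuisance] <- logit_mu[, nuisance] +
      1.5 * matrix(stats::rnorm(n * length(nuisance)), n, length(nuisance))
  }
  mu <- stats::plogis(logit_mu)
  meth <- matrix(stats::rbeta(n * p_meth, mu * kappa, (1 - mu) * kappa),
                 n, p_meth)
  # XOR pairs: dichotomized latents whose parity tracks the class
  if (nrow(pair_cols)) {
    for (k in seq_len(nrow(pair_cols))) {
      d1 <- stats::rbinom(n, 1L, 0.5)
      flip <- stats::rbinom(n, 1L, cfg$label_noise)
      d2 <- bitwXor(bitwXor(d1, cls), flip)
      for (j in 1:2) {
        d <- if (j == 1) d1 else d2
        mu_pair <- ifelse(d == 1L, 0.8, 0.2)
        meth[, pair_cols[k, j]] <-
          stats::rbeta(n, mu_pair * kappa, (1 - mu_pair) * kappa)
      }
    }
  }
  colnames(meth) <- sprintf("cg%06d", seq_len(p_meth))

  ## expression block -----------------------------------------------------
  set.seed(stream[["expr"]])
  log_base <- stats::rnorm(p_expr, log(10), 1)
  log_mu <- matrix(log_base, n, p_expr, byrow = TRUE)
  if (n_inf_expr > 0)
    log_mu[, inf_expr] <- log_mu[, inf_expr] +
      outer(cls - 0.5, rep(cfg$effect_size, n_inf_expr))
  expr <- matrix(exp(log_mu + stats::rnorm(n * p_expr, 0, 0.5)), n, p_expr)
  colnames(expr) <- sprintf("GENE%04d", seq_len(p_expr))

  ## covariates -----------------------------------------------------------
  set.seed(stream[["covariates"]])
  covariates <- data.frame(
    age = round(stats::rnorm(n, 60, 10)),
    gender = sample(c("female", "male"), n, replace = TRUE),
    grade = sample(c("II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.2, 0.3, 0.5)))

  ## synthetic probe coordinates (for region construction) ---------------
  set.seed(stream[["coords"]])
  probes <- data.frame(
    probe_id = colnames(meth),
    chrom = sample(paste0("chr", 1:22), p_meth, replace = TRUE),
    pos_1based = sample.int(5e7, p_meth))

  sample_ids <- sprintf("S%04d", seq_len(n))
  values <- cbind(meth, expr)
  rownames(values) <- sample_ids
  ds <- omics_dataset(values,
                      feature_kind = c(rep("methylation", p_meth),
                                       rep("expression", p_expr)),
                      survival_days = days, covariates = covariates)
  ds <- suppressMessages(assign_classes(ds, class_rule(cfg$threshold_days)))

  informative_ids <- c(colnames(meth)[inf_meth], colnames(expr)[inf_expr])
  truth <- structure(list(
    informative_ids = informative_ids,
    interacting_pairs = if (nrow(pair_cols))
      matrix(colnames(meth)[pair_cols], ncol = 2) else
      matrix(character(0), ncol = 2),
    effect_sizes = stats::setNames(rep(cfg$effect_size, length(informative_ids)),
                                   informative_ids),
    class = ds$class_label,
    config = cfg), class = "synthetic_truth")

  list(dataset = ds, truth = truth, probes = probes)
}
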