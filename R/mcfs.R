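#' MCFS configuration
#'
#' Parameters of the Monte Carlo Feature Selection run. The published
#' full-scale settings for the glioma decision system are `s = 50000`,
#' `m = 500`, `t = 5` with all remaining parameters at their defaults
#' (`u = v = 1`); desk-scale analyses use much smaller `s`.
#'
#' @param s number of random feature subsets (projections).
#' @param m features drawn (without replacement) per subset.
#' @param t trees (stratified train/test splits) per subset.
#' @param u exponent on the tree's weighted (balanced) accuracy in RI.
#' @param v exponent on the node's training-sample fraction in RI.
#' @param split_fraction share of samples in the training part (2/3,
#'   stratified by class).
#' @param max_depth tree depth cap (`Inf` = grow until `min_split`).
#' @param min_split minimum node size eligible for splitting (default 20,
#'   the conventional CART stopping rule); smaller nodes become leaves.
#' @param impurity `"entropy"` (information gain, canonical) or `"gini"`.
#' @param id_weighting `"ig"` (edge contributions IG(node)/distance,
#'   default) or `"count"` (1/distance) for the interdependency graph.
#' @param epsilon minimal gain required to split (1e-9); ties between
#'   splits break to the lowest feature index, then lowest threshold.
#' @export
mcfs_config <- function(s = 50000L, m = 500L, t = 5L, u = 1, v = 1,
                        split_fraction = 2 / 3, max_depth = Inf,
                        min_split = 20L,
                        impurity = c("entropy", "gini"),
                        id_weighting = c("ig", "count"),
                        epsilon = 1e-9) {
  impurity <- match.arg(impurity)
  id_weighting <- match.arg(id_weighting)
  if (any(c(s, m, t) < 1)) stop("s, m and t must be >= 1")
  if (u < 0 || v < 0) stop("u and v must be non-negative")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("`split_fraction` must lie in (0, 1)")
  if (min_split < 2) stop("`min_split` must be >= 2")
  structure(list(s = as.integer(s), m = as.integer(m), t = as.integer(t),
                 u = u, v = v, split_fraction = split_fraction,
                 max_depth = max_depth, min_split = as.integer(min_split),
                 impurity = impurity, id_weighting = id_weighting,
                 epsilon = epsilon),
            class = "mcfs_config")
}

as_binary_class <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("exactly two classes are required")
  as.integer(y) - 1L
}

#' Grow a single decision tree
#'
#' Binary classification tree grown greedily by maximal impurity decrease
#' (information gain by default) over axis-aligned splits, with thresholds
#' at midpoints between consecutive sorted unique values. Growth stops at
#' purity, the depth cap, or when no split gains more than `epsilon`.
#' Every internal node records its split feature, threshold, gain, and the
#' number of training samples reaching it — the raw material of the RI and
#' ID statistics.
#'
#' @param x numeric matrix (samples x features).
#' @param y two-level class vector.
#' @param cfg an [mcfs_config()] (only `max_depth`, `impurity`, `epsilon`
#'   are used here).
#' @return an `mcfs_tree`: list of parallel node vectors (`feature` id,
#'   `threshold`, `ig`, `count`, `parent`, `depth`, `left`, `right`,
#'   `pred`) plus `wacc` (NA until evaluated) and `feature_ids`.
#' @export
build_tree <- function(x, y, cfg = mcfs_config()) {
  x <- as.matrix(x)
  yf <- as.factor(y)
  if (nlevels(yf) > 2) stop("at most two classes are supported")
  yy <- as.integer(yf) - 1L  # single-class input yields a degenerate leaf
  if (ncol(x) < 1) stop("at least one feature is required")
  tr <- cpp_build_tree(x, yy, seq_len(nrow(x)), seq_len(ncol(x)),
                       cfg$epsilon, cfg$max_depth, cfg$min_split,
                       cfg$impurity == "gini")
  tr$feature_ids <- colnames(x)
  tr$class_levels <- if (nlevels(yf) == 2) levels(yf) else
    c(levels(yf), ".other")
  tr$degenerate <- all(is.na(tr$feature))
  class(tr) <- "mcfs_tree"
  tr
}

#' @export
print.mcfs_tree <- function(x, ...) {
  n_int <- sum(!is.na(x$feature))
  cat("mcfs_tree:", length(x$feature), "nodes (", n_int, "internal ),",
      "depth", max(x$depth), "\n")
  if (!is.na(x$wacc)) cat("  held-out weighted accuracy:", round(x$wacc, 4), "\n")
  invisible(x)
}

#' @export
predict.mcfs_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  cls <- cpp_predict_tree(unclass(object), newdata)
  factor(object$class_levels[cls + 1L], levels = object$class_levels)
}

#' Weighted (balanced) accuracy from a 2x2 confusion matrix
#'
#' The mean of the two per-class recalls: `0.5 * (TP/(TP+FN) + TN/(TN+FP))`
#' with true classes in rows. Robust to class imbalance; this is the
#' `wAcc` that weights each tree's contribution to RI.
#'
#' @param conf 2x2 numeric matrix of counts, true classes in rows,
#'   predictions in columns.
#' @return a number in \[0, 1\].
#' @export
weighted_accuracy <- function(conf) {
  conf <- as.matrix(conf)
  stopifnot(nrow(conf) == 2, ncol(conf) == 2)
  rs <- rowSums(conf)
  if (any(rs == 0)) stop("each true class needs at least one sample")
  mean(diag(conf) / rs)
}

#' Run the Monte Carlo projections and keep the scored trees
#'
#' Reference-scale variant of the projection loop: `s` random feature
#' subsets of size `m`, each with `t` stratified train/test splits, a tree
#' per split scored by held-out weighted accuracy. The full tree collection
#' is returned, suitable for [compute_ri()] / [accumulate_id()] and for
#' inspection; [mcfs()] runs the same loop with streaming accumulation and
#' should be preferred at scale.
#'
#' @param ds an [omics_dataset()] with classes assigned, or a numeric
#'   matrix (then `y` is required).
#' @param cfg an [mcfs_config()].
#' @param y class vector when `ds` is a matrix.
#' @param seed integer seed.
#' @return list of `mcfs_tree` objects of length `s * t`.
#' @export
run_projections <- function(ds, cfg = mcfs_config(), y = NULL, seed = NULL) {
  xy <- resolve_xy(ds, y)
  if (cfg$m > ncol(xy$x))
    stop("m (", cfg$m, ") exceeds the number of features (", ncol(xy$x), ")")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_mcfs(xy$x, xy$y, cfg$s, cfg$m, cfg$t, cfg$u, cfg$v,
                      cfg$split_fraction, cfg$max_depth, cfg$min_split,
                      cfg$epsilon, cfg$impurity == "gini",
                      cfg$id_weighting == "ig", keep_trees = TRUE)
  lapply(res$trees, function(tr) {
    tr$feature_ids <- colnames(xy$x)
    tr$class_levels <- xy$levels
    tr$degenerate <- all(is.na(tr$feature))
    class(tr) <- "mcfs_tree"
    tr
  })
}

resolve_xy <- function(ds, y) {
  if (inherits(ds, "omics_dataset")) {
    if (is.null(ds$class_label))
      stop("assign classes first (see assign_classes())")
    list(x = ds$values, y = as.integer(ds$class_label) - 1L,
         levels = levels(ds$class_label))
  } else {
    if (is.null(y)) stop("`y` is required when `ds` is a matrix")
    x <- as.matrix(ds)
    if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
    list(x = x, y = as_binary_class(y), levels = levels(as.factor(y)))
  }
}

#' Aggregate relative importance over a tree collection
#'
#' The RI of feature g is the sum, over all scored trees tau and all nodes
#' splitting on g, of `wAcc(tau)^u * IG(node) * (count(node)/count(root))^v`.
#' Features never sampled into any projection get RI 0 (their number is
#' reported via a message). The aggregation is additive over tree
#' collections, which is what makes streaming accumulation exact.
#'
#' @param trees list of scored `mcfs_tree` objects (with `wacc` set).
#' @param cfg an [mcfs_config()] supplying `u` and `v`.
#' @param feature_ids optional full feature universe (ids never appearing
#'   in `trees` receive RI 0).
#' @return an `ri_ranking` data.frame: `feature`, `ri`, `rank` (1 = best);
#'   see [determine_cutoff()] for significance flags.
#' @export
compute_ri <- function(trees, cfg = mcfs_config(), feature_ids = NULL) {
  if (is.null(feature_ids))
    feature_ids <- unique(unlist(lapply(trees, `[[`, "feature_ids")))
  ri <- stats::setNames(numeric(length(feature_ids)), feature_ids)
  n_deg <- 0L
  for (tr in trees) {
    internal <- which(!is.na(tr$feature))
    if (!length(internal) || is.na(tr$wacc)) { n_deg <- n_deg + 1L; next }
    wu <- tr$wacc^cfg$u
    contrib <- wu * tr$ig[internal] *
      (tr$count[internal] / tr$count[1])^cfg$v
    ids <- tr$feature_ids[tr$feature[internal]]
    for (k in seq_along(ids)) ri[[ids[k]]] <- ri[[ids[k]]] + contrib[k]
  }
  if (n_deg > 0) message(n_deg, " degenerate tree(s) contributed no RI")
  ri_ranking(ri)
}

ri_ranking <- function(ri, cutoff = NA_real_) {
  ord <- order(-ri, names(ri), method = "radix")
  out <- data.frame(feature = names(ri)[ord], ri = unname(ri[ord]),
                    rank = seq_along(ri),
                    significant = if (is.na(cutoff)) NA else unname(ri[ord]) > cutoff,
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("ri_ranking", "data.frame")
  out
}

#' Permutation significance cutoff for the RI ranking
#'
#' Class labels are permuted `n_perm` times; a (typically reduced-`s`) MCFS
#' run on each permutation records the maximal RI any feature attains under
#' the null of no class association. Because RI is an unnormalised sum over
#' trees, each permutation maximum is rescaled by `s / s_perm` before the
#' cutoff is formed as the upper one-sided Student-t confidence bound of
#' the rescaled max-RI sample: `mean + qt(confidence, n_perm - 1) * sd /
#' sqrt(n_perm)`. Features whose real-data RI exceeds the cutoff are
#' flagged significant.
#'
#' @param ds dataset (or matrix, with `y`).
#' @param cfg the [mcfs_config()] of the main run.
#' @param n_perm number of permutations (>= 2; default 20).
#' @param confidence confidence level of the bound (default 0.95).
#' @param s_perm projections per permutation run (default `ceiling(s/10)`).
#' @param y class vector when `ds` is a matrix.
#' @param seed integer seed.
#' @return list with `cutoff_value`, the per-permutation (rescaled)
#'   `max_ri` sample, and the settings used.
#' @export
determine_cutoff <- function(ds, cfg = mcfs_config(), n_perm = 20L,
                             confidence = 0.95,
                             s_perm = max(1L, ceiling(cfg$s / 10)),
                             y = NULL, seed = NULL) {
  if (n_perm < 2) stop("`n_perm` must be >= 2")
  xy <- resolve_xy(ds, y)
  if (!is.null(seed)) set.seed(seed)
  perm_cfg <- cfg
  perm_cfg$s <- as.integer(s_perm)
  max_ri <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- sample(xy$y)
    res <- cpp_run_mcfs(xy$x, yp, perm_cfg$s, perm_cfg$m, perm_cfg$t,
                        perm_cfg$u, perm_cfg$v, perm_cfg$split_fraction,
                        perm_cfg$max_depth, perm_cfg$min_split,
                        perm_cfg$epsilon, perm_cfg$impurity == "gini",
                        perm_cfg$id_weighting == "ig", FALSE)
    max_ri[b] <- max(res$ri) * (cfg$s / perm_cfg$s)
  }
  if (stats::sd(max_ri) == 0) {
    warning("degenerate max-RI sample (all equal); cutoff set to that value")
    cutoff <- max_ri[1]
  } else {
    cutoff <- mean(max_ri) +
      stats::qt(confidence, n_perm - 1) * stats::sd(max_ri) / sqrt(n_perm)
  }
  list(cutoff_value = cutoff, max_ri = max_ri, n_perm = n_perm,
       confidence = confidence, s_perm = perm_cfg$s)
}

#' Fit Monte Carlo Feature Selection with Interdependency Discovery
#'
#' The main fitting function. Grows `s * t` decision trees on random
#' feature subsets and stratified sample splits, aggregates each feature's
#' relative importance (RI) weighted by tree quality, builds the directed
#' interdependency (ID) graph from split co-occurrence along tree paths,
#' and (optionally) sets a permutation-based significance cutoff on the
#' ranking.
#'
#' @param x samples x features numeric matrix, an [omics_dataset()] with
#'   classes assigned, or a formula `class ~ .` with `data`.
#' @param y two-level class vector (ignored for datasets/formulas).
#' @param cfg an [mcfs_config()].
#' @param cutoff `"permutation"` to compute the significance cutoff,
#'   `"none"` to skip it.
#' @param n_perm,confidence,s_perm forwarded to [determine_cutoff()].
#' @param seed integer seed driving the whole run.
#' @param ... method-specific arguments.
#' @return an object of class `mcfs` with components `ri` (the
#'   `ri_ranking` data.frame), `id_graph` (an [id_graph()]), `wacc`
#'   (per-tree held-out weighted accuracies), `cutoff` (the
#'   [determine_cutoff()] record or NULL), `cfg`, `call`.
#' @examples
#' sim <- generate_dataset(synth_config(n_samples = 60, n_meth_features = 40,
#'                                      n_expr_features = 10, n_informative = 4,
#'                                      effect_size = 2, seed = 7))
#' fit <- mcfs(sim$dataset, cfg = mcfs_config(s = 100, m = 10, t = 3),
#'             cutoff = "none", seed = 7)
#' head(fit$ri)
#' @export
mcfs <- function(x, ...) UseMethod("mcfs")

#' @rdname mcfs
#' @export
mcfs.default <- function(x, y = NULL, cfg = mcfs_config(),
                         cutoff = c("permutation", "none"), n_perm = 20L,
                         confidence = 0.95,
                         s_perm = max(1L, ceiling(cfg$s / 10)),
                         seed = NULL, ...) {
  cutoff <- match.arg(cutoff)
  xy <- resolve_xy(x, y)
  if (cfg$m > ncol(xy$x))
    stop("m (", cfg$m, ") exceeds the number of features (", ncol(xy$x), ")")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_mcfs(xy$x, xy$y, cfg$s, cfg$m, cfg$t, cfg$u, cfg$v,
                      cfg$split_fraction, cfg$max_depth, cfg$min_split,
                      cfg$epsilon, cfg$impurity == "gini",
                      cfg$id_weighting == "ig", FALSE)
  ri <- stats::setNames(res$ri, colnames(xy$x))
  never <- sum(res$sampled == 0L)
  if (never > 0)
    message(never, " feature(s) never sampled into a projection; RI set to 0")

  cut_rec <- NULL
  if (cutoff == "permutation") {
    cut_rec <- determine_cutoff(xy$x, cfg, n_perm = n_perm,
                                confidence = confidence, s_perm = s_perm,
                                y = xy$y)
  }
  ranking <- ri_ranking(ri, cutoff = if (is.null(cut_rec)) NA_real_
                                     else cut_rec$cutoff_value)
  graph <- id_graph(
    data.frame(from = colnames(xy$x)[res$edge_from],
               to = colnames(xy$x)[res$edge_to],
               weight = res$edge_weight, count = res$edge_count,
               stringsAsFactors = FALSE),
    ri = ri)

  structure(list(ri = ranking, id_graph = graph, wacc = res$wacc,
                 n_degenerate = res$n_degenerate, cutoff = cut_rec,
                 cfg = cfg, n = nrow(xy$x), p = ncol(xy$x),
                 class_levels = xy$levels, call = match.call()),
            class = "mcfs")
}

#' @rdname mcfs
#' @export
mcfs.omics_dataset <- function(x, ...) mcfs.default(x, ...)

#' @rdname mcfs
#' @param data data.frame holding the formula variables.
#' @export
mcfs.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  xm <- as.matrix(mf[, -1, drop = FALSE])
  mcfs.default(xm, y = y, ...)
}

#' @export
print.mcfs <- function(x, ...) {
  cat("Monte Carlo Feature Selection (MCFS-ID)\n")
  cat(sprintf("  %d samples x %d features; s = %d, m = %d, t = %d (%d trees)\n",
              x$n, x$p, x$cfg$s, x$cfg$m, x$cfg$t, length(x$wacc)))
  cat(sprintf("  mean held-out weighted accuracy: %.3f\n",
              mean(x$wacc, na.rm = TRUE)))
  if (!is.null(x$cutoff))
    cat(sprintf("  cutoff %.4g -> %d significant feature(s)\n",
                x$cutoff$cutoff_value, sum(x$ri$significant)))
  cat("  top features:\n")
  print(utils::head(x$ri, 5), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mcfs <- function(object, top = 10L, ...) {
  out <- list(ranking = utils::head(object$ri, top),
              n_significant = if (is.null(object$cutoff)) NA_integer_
                              else sum(object$ri$significant),
              cutoff = object$cutoff$cutoff_value,
              wacc = summary(object$wacc),
              top_edges = top_edges(object$id_graph,
                                    min(10L, nrow(object$id_graph$edges))),
              cfg = object$cfg)
  class(out) <- "summary.mcfs"
  out
}

#' @export
print.summary.mcfs <- function(x, ...) {
  cat("MCFS-ID summary\n\nTop of the RI ranking:\n")
  print(x$ranking, row.names = FALSE)
  if (!is.na(x$n_significant))
    cat(sprintf("\n%d feature(s) above the cutoff %.4g\n",
                x$n_significant, x$cutoff))
  cat("\nHeld-out weighted accuracy of the trees:\n")
  print(x$wacc)
  if (nrow(x$top_edges)) {
    cat("\nStrongest interdependencies:\n")
    print(x$top_edges, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.mcfs <- function(object, ...) {
  stats::setNames(object$ri$ri, object$ri$feature)
}

#' Plot the RI ranking
#'
#' Bar plot of the top features' relative importance; significant features
#' (above the permutation cutoff, drawn as a dashed line) in red, the rest
#' grey.
#'
#' @param x an `mcfs` fit.
#' @param top number of top features to draw.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.mcfs <- function(x, top = 30L, ...) {
  d <- utils::head(x$ri, top)
  cols <- if (all(is.na(d$significant))) "grey40"
          else ifelse(d$significant, "firebrick", "grey70")
  graphics::barplot(rev(d$ri), names.arg = rev(d$feature), horiz = TRUE,
                    col = rev(cols), las = 1, xlab = "Relative importance",
                    cex.names = 0.6, ...)
  if (!is.null(x$cutoff))
    graphics::abline(v = x$cutoff$cutoff_value, lty = 2)
  invisible(x)
}

#' Significant features of an MCFS fit
#'
#' @param fit an `mcfs` object fitted with `cutoff = "permutation"`.
#' @return character vector of feature ids above the cutoff, best first.
#' @export
significant_features <- function(fit) {
  stopifnot(inherits(fit, "mcfs"))
  if (is.null(fit$cutoff)) stop("fit has no cutoff; rerun with cutoff = \"permutation\"")
  fit$ri$feature[fit$ri$significant]
}

#' Write an RI ranking as TSV
#'
#' @param ranking an `ri_ranking` (e.g. `fit$ri`).
#' @param path output path.
#' @export
write_ri <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
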