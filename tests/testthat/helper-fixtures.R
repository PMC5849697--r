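# Shared fixtures and independent oracles used across the suite.

# tiny assembled dataset with classes assigned
tiny_dataset <- function(n = 20, p_meth = 6, p_expr = 2, seed = 42) {
  set.seed(seed)
  meth <- matrix(runif(n * p_meth), n, p_meth,
                 dimnames = list(sprintf("S%02d", 1:n),
                                 sprintf("cg%03d", 1:p_meth)))
  expr <- matrix(rexp(n * p_expr, 1 / 10), n, p_expr,
                 dimnames = list(rownames(meth), sprintf("G%02d", 1:p_expr)))
  days <- sample(c(50:350, 450:900), n)
  ds <- omics_dataset(cbind(meth, expr),
                      feature_kind = c(rep("methylation", p_meth),
                                       rep("expression", p_expr)),
                      survival_days = days,
                      covariates = data.frame(age = rnorm(n, 60, 8),
                                              gender = sample(c("f", "m"), n, TRUE)))
  suppressMessages(assign_classes(ds, class_rule(400)))
}

# hand-built mcfs_tree: node vectors given explicitly
manual_tree <- function(feature, threshold, ig, count, parent, depth,
                        wacc, feature_ids, left = NULL, right = NULL) {
  structure(list(feature = feature, threshold = threshold, ig = ig,
                 count = count, parent = parent, depth = depth,
                 left = left, right = right,
                 pred = rep(0L, length(feature)), wacc = wacc,
                 feature_ids = feature_ids,
                 class_levels = c("SHORT", "LONG"),
                 degenerate = all(is.na(feature))),
            class = "mcfs_tree")
}

# independent reference tree grower: exhaustive split enumeration at every
# node in plain R (midpoint thresholds, max information gain, ties to the
# lowest feature index then lowest threshold)
entropy_bits <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_best_split <- function(x, y) {
  best <- list(gain = 0, feature = NA, threshold = NA)
  h <- entropy_bits(y)
  for (f in seq_len(ncol(x))) {
    v <- sort(unique(x[, f]))
    if (length(v) < 2) next
    for (thr in (v[-length(v)] + v[-1]) / 2) {
      l <- x[, f] <= thr
      gain <- h - mean(l) * entropy_bits(y[l]) - mean(!l) * entropy_bits(y[!l])
      if (gain > best$gain + 1e-12)
        best <- list(gain = gain, feature = f, threshold = thr)
    }
  }
  best
}

oracle_tree_acc <- function(x, y, depth, min_split = 2) {
  # training accuracy of the greedily grown tree, exhaustive splits
  grow_acc <- function(x, y, d) {
    maj <- max(table(y)) / length(y)
    if (d == 0 || length(unique(y)) == 1 || length(y) < min_split) return(maj)
    sp <- oracle_best_split(x, y)
    if (is.na(sp$feature) || sp$gain <= 1e-9) return(maj)
    l <- x[, sp$feature] <= sp$threshold
    mean(l) * grow_acc(x[l, , drop = FALSE], y[l], d - 1) +
      mean(!l) * grow_acc(x[!l, , drop = FALSE], y[!l], d - 1)
  }
  grow_acc(x, y, depth)
}

tree_training_accuracy <- function(tree, x, y) {
  mean(as.character(predict(tree, x)) == as.character(y))
}

# quadratic all-pairs interval overlap oracle (0-based half-open)
oracle_overlaps <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    same <- which(b$chrom == a$chrom[i])
    ov <- pmin(a$end[i], b$end[same]) - pmax(a$start[i], b$start[same])
    hit <- same[ov > 0]
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(region = a$name[i],
                                           annotation = b$name[hit])
  }
  if (!length(out)) return(data.frame(region = character(0),
                                      annotation = character(0)))
  do.call(rbind, out)
}
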