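#' Survival-histogram threshold scan
#'
#' Histograms the days-to-death and, for every candidate threshold (bin
#' edge) inside `scan_range`, computes a drop statistic: mean bin count
#' below the candidate minus mean bin count above it (both restricted to
#' `scan_range`). A persistent drop in the histogram around some day value
#' shows up as a high-ranking candidate; the choice of the classification
#' threshold remains the caller's.
#'
#' @param days positive integer day vector.
#' @param bin_width histogram bin width in days (default 50).
#' @param scan_range numeric length-2: candidate thresholds considered
#'   (default `c(100, 1000)` — the region of interest below 1000 days).
#' @return list with `histogram` (data.frame `bin_start`, `bin_end`,
#'   `count`) and `candidates` (data.frame `threshold`, `drop`, sorted by
#'   drop descending).
#' @export
survival_histogram_scan <- function(days, bin_width = 50L,
                                    scan_range = c(100, 1000)) {
  if (any(days <= 0)) stop("`days` must be positive")
  if (scan_range[1] >= scan_range[2] ||
      scan_range[1] > max(days) || scan_range[2] < min(days))
    stop("`scan_range` lies outside the data range")
  breaks <- seq(0, max(days) + bin_width, by = bin_width)
  counts <- as.vector(table(cut(days, breaks, right = TRUE)))
  hist_df <- data.frame(bin_start = breaks[-length(breaks)],
                        bin_end = breaks[-1], count = counts)
  in_scan <- hist_df$bin_start >= scan_range[1] - bin_width &
             hist_df$bin_end <= scan_range[2] + bin_width
  cand_edges <- breaks[breaks >= scan_range[1] & breaks <= scan_range[2]]
  cand_edges <- setdiff(cand_edges, range(breaks))
  drops <- vapply(cand_edges, function(thr) {
    below <- hist_df$count[in_scan & hist_df$bin_end <= thr]
    above <- hist_df$count[in_scan & hist_df$bin_start >= thr]
    if (!length(below) || !length(above)) return(NA_real_)
    mean(below) - mean(above)
  }, 0)
  cand <- data.frame(threshold = cand_edges, drop = drops)
  cand <- cand[!is.na(cand$drop), , drop = FALSE]
  cand <- cand[order(-cand$drop), , drop = FALSE]
  rownames(cand) <- NULL
  list(histogram = hist_df, candidates = cand)
}

#' Methylation stratification rule
#'
#' Three-way labelling of samples by a probe's beta-value: High when
#' beta > `high_threshold`, Low when beta < `low_threshold`, Medium on the
#' closed interval between them. Defaults 0.96 / 0.85 are the strata used
#' for the top prognostic CpG.
#'
#' @param high_threshold,low_threshold beta-value cutpoints.
#' @export
strata_rule <- function(high_threshold = 0.96, low_threshold = 0.85) {
  if (low_threshold > high_threshold)
    stop("`low_threshold` must not exceed `high_threshold`")
  structure(list(high_threshold = high_threshold,
                 low_threshold = low_threshold), class = "strata_rule")
}

#' Stratify samples by a probe's beta-value
#'
#' @param beta per-sample beta-values in \[0, 1\].
#' @param rule a [strata_rule()].
#' @return factor with levels `Low`, `Medium`, `High`.
#' @export
stratify_by_beta <- function(beta, rule = strata_rule()) {
  if (any(beta < 0 | beta > 1)) stop("beta-values must lie in [0, 1]")
  lab <- ifelse(beta > rule$high_threshold, "High",
                ifelse(beta < rule$low_threshold, "Low", "Medium"))
  factor(lab, levels = c("Low", "Medium", "High"))
}

#' Kaplan-Meier product-limit estimate per stratum
#'
#' Wraps [survival::survfit()]: `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`
#' over the event times, with right-censoring supported (the glioma
#' cohorts this targets are all-deceased, but censoring is needed for
#' general reuse).
#'
#' @param days event/censoring times.
#' @param events 0/1 event indicators (default all 1).
#' @param strata optional factor of stratum labels (e.g. from
#'   [stratify_by_beta()]).
#' @return a `km_curves` object: data.frame with `stratum`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(days, events = rep(1L, length(days)), strata = NULL) {
  if (is.null(strata)) strata <- factor(rep("all", length(days)))
  strata <- droplevels(as.factor(strata))
  fit <- survival::survfit(survival::Surv(days, events) ~ strata)
  if (nlevels(strata) == 1) {
    stratum <- rep(levels(strata), length(fit$time))
  } else {
    stratum <- rep(sub("^strata=", "", names(fit$strata)), fit$strata)
  }
  out <- data.frame(stratum = stratum, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, stringsAsFactors = FALSE)
  class(out) <- c("km_curves", "data.frame")
  out
}

#' @export
print.km_curves <- function(x, ...) {
  for (s in unique(x$stratum)) {
    d <- x[x$stratum == s, , drop = FALSE]
    cat(sprintf("stratum %s: %d time point(s), %d event(s), median survival %s\n",
                s, nrow(d), sum(d$n_event),
                format(suppressWarnings(min(d$time[d$surv <= 0.5])))))
  }
  invisible(x)
}

#' Plot Kaplan-Meier curves
#'
#' Step-function survival curves per stratum with an optional vertical
#' marker (by default the 400-day class boundary).
#'
#' @param x a `km_curves` object.
#' @param mark_day vertical reference line in days (NA to omit).
#' @param col colours, one per stratum.
#' @param ... passed to [plot()].
#' @export
plot.km_curves <- function(x, mark_day = 400, col = NULL, ...) {
  strata <- unique(x$stratum)
  if (is.null(col)) col <- seq_along(strata)
  plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1),
       xlab = "Days", ylab = "Survival probability", ...)
  for (i in seq_along(strata)) {
    d <- x[x$stratum == strata[i], , drop = FALSE]
    graphics::lines(stats::stepfun(d$time, c(1, d$surv)), do.points = FALSE,
                    col = col[i])
  }
  if (!is.na(mark_day)) graphics::abline(v = mark_day, lty = 2)
  graphics::legend("topright", legend = strata, col = col, lty = 1, bty = "n")
  invisible(x)
}

#' Log-rank test between two survival strata
#'
#' Standard log-rank via [survival::survdiff()] (`rho = 0`): observed vs
#' expected events under the pooled hazard, hypergeometric variance,
#' chi-square with 1 df. The default comparison for beta-value strata is
#' High vs Low with the Medium stratum excluded.
#'
#' @param days event/censoring times.
#' @param events 0/1 event indicators.
#' @param group factor of group labels.
#' @param compare length-2 character: which two groups to compare (default
#'   the first and last level, i.e. Low vs High for [stratify_by_beta()]
#'   output).
#' @return list with `chisq`, `df` (= 1), `p_value`, and the per-group
#'   observed/expected table.
#' @export
log_rank_test <- function(days, events = rep(1L, length(days)), group,
                          compare = NULL) {
  group <- as.factor(group)
  if (is.null(compare)) compare <- levels(group)[c(1, nlevels(group))]
  sel <- group %in% compare
  g <- droplevels(group[sel])
  if (nlevels(g) < 2) stop("both comparison groups must be non-empty")
  d <- days[sel]; e <- events[sel]
  if (sum(e) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(chisq = 0, df = 1L, p_value = 1,
                table = data.frame(group = levels(g), observed = 0,
                                   expected = 0)))
  }
  sd_fit <- survival::survdiff(survival::Surv(d, e) ~ g)
  chisq <- unname(sd_fit$chisq)
  list(chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       table = data.frame(group = levels(g), observed = sd_fit$obs,
                          expected = sd_fit$exp))
}

#' Kaplan-Meier analysis of one methylation probe
#'
#' The full per-probe survival workflow: stratify by beta-value, estimate
#' KM curves per stratum, and test High vs Low by log-rank.
#'
#' @param ds an [omics_dataset()].
#' @param probe methylation feature id.
#' @param rule a [strata_rule()].
#' @return list with `strata`, `curves` (a `km_curves`), and `logrank`.
#' @export
km_probe_analysis <- function(ds, probe, rule = strata_rule()) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (!probe %in% colnames(ds$values)) stop("unknown probe: ", probe)
  strata <- stratify_by_beta(ds$values[, probe], rule)
  curves <- km_estimate(ds$survival_days, ds$event, strata)
  lr <- if (all(c("Low", "High") %in% strata))
    log_rank_test(ds$survival_days, ds$event, strata,
                  compare = c("Low", "High")) else NULL
  list(probe = probe, strata = strata, curves = curves, logrank = lr)
}
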