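#' Omics dataset container
#'
#' Bundles a samples x features value matrix (methylation beta-values,
#' expression, numerically encoded clinical covariates) with per-sample
#' survival information and an optional binary survival class. This is the
#' object every downstream stage of the pipeline consumes.
#'
#' Invariants enforced at construction: unique sample and feature ids, no
#' missing values, methylation values in \[0, 1\], expression values >= 0,
#' and (when assigned) a class label that is a deterministic function of
#' `survival_days` and the day threshold of the [class_rule()] used.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids).
#' @param feature_kind character vector, one of `"methylation"`,
#'   `"expression"`, `"clinical"` per column of `values`.
#' @param survival_days non-negative integer vector, days to death (or last
#'   follow-up for censored samples), one per sample.
#' @param event 0/1 vector, 1 = deceased. Defaults to all 1 (the cohorts
#'   this pipeline targets include deceased patients only).
#' @param covariates optional data.frame of per-sample covariates
#'   (e.g. `age`, `gender`, `grade`), rownames matching sample ids.
#' @param class_label optional factor with the SHORT/LONG survival class;
#'   normally set by [assign_classes()], not by hand.
#' @param class_rule the [class_rule()] that produced `class_label`.
#' @return an object of class `omics_dataset`.
#' @seealso [load_feature_table()], [assemble_dataset()],
#'   [drop_zero_variance()], [assign_classes()]
#' @export
omics_dataset <- function(values, feature_kind, survival_days,
                          event = rep(1L, nrow(values)), covariates = NULL,
                          class_label = NULL, class_rule = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values))
    stop("`values` contains missing entries; apply the missing-value policy first")

  feature_kind <- rep_len(as.character(feature_kind), ncol(values))
  bad_kind <- setdiff(unique(feature_kind), c("methylation", "expression", "clinical"))
  if (length(bad_kind))
    stop("unknown feature kind(s): ", paste(bad_kind, collapse = ", "))
  names(feature_kind) <- colnames(values)
  check_kind_ranges(values, feature_kind)

  survival_days <- as.integer(round(survival_days))
  if (length(survival_days) != nrow(values) || any(survival_days < 0))
    stop("`survival_days` must be one non-negative integer per sample")
  event <- as.integer(event)
  if (length(event) != nrow(values) || !all(event %in% c(0L, 1L)))
    stop("`event` must be a 0/1 vector, one per sample")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values))
      stop("`covariates` must have one row per sample")
    rownames(covariates) <- rownames(values)
  }
  if (!is.null(class_label)) {
    class_label <- as.factor(class_label)
    if (length(class_label) != nrow(values))
      stop("`class_label` must have one entry per sample")
  }

  structure(
    list(values = values, feature_kind = feature_kind,
         survival_days = stats::setNames(survival_days, rownames(values)),
         event = stats::setNames(event, rownames(values)),
         covariates = covariates, class_label = class_label,
         class_rule = class_rule),
    class = "omics_dataset")
}

check_kind_ranges <- function(values, feature_kind) {
  meth <- which(feature_kind == "methylation")
  if (length(meth)) {
    bad <- which(values[, meth, drop = FALSE] < 0 | values[, meth, drop = FALSE] > 1,
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf(
        "methylation beta-value out of [0,1]: value %g at sample '%s', feature '%s'",
        values[bad[1, 1], meth[bad[1, 2]]],
        rownames(values)[bad[1, 1]], colnames(values)[meth[bad[1, 2]]]))
  }
  expr <- which(feature_kind == "expression")
  if (length(expr)) {
    bad <- which(values[, expr, drop = FALSE] < 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf(
        "negative expression value %g at sample '%s', feature '%s'",
        values[bad[1, 1], expr[bad[1, 2]]],
        rownames(values)[bad[1, 1]], colnames(values)[expr[bad[1, 2]]]))
  }
  invisible(TRUE)
}

#' @export
print.omics_dataset <- function(x, ...) {
  kinds <- table(factor(x$feature_kind,
                        levels = c("methylation", "expression", "clinical")))
  cat("omics_dataset:", nrow(x$values), "samples x", ncol(x$values), "features\n")
  cat("  methylation:", kinds[["methylation"]],
      " expression:", kinds[["expression"]],
      " clinical:", kinds[["clinical"]], "\n")
  if (!is.null(x$class_label)) {
    cat("  classes:",
        paste(sprintf("%s=%d", levels(x$class_label), table(x$class_label)),
              collapse = ", "), "\n")
  } else {
    cat("  classes: unassigned\n")
  }
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) dim(x$values)

#' Read one samples x features block from a tab-separated file
#'
#' The expected layout is the TCGA level-3 style matrix: first column the
#' sample identifier, header row the feature identifiers, tab-separated
#' numeric values. Range checks appropriate to `kind` are applied
#' immediately (beta-values in \[0, 1\], expression >= 0), and any
#' non-numeric cell is reported by sample and feature id.
#'
#' @param path file path.
#' @param kind `"methylation"`, `"expression"` or `"clinical"`.
#' @return a `feature_block`: list with `values` (numeric matrix) and `kind`.
#' @export
load_feature_table <- function(path, kind = c("methylation", "expression", "clinical")) {
  kind <- match.arg(kind)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("expected a sample-id column plus >= 1 feature column")
  sample_ids <- raw[[1]]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  feature_ids <- colnames(raw)[-1]
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(sample_ids, feature_ids))
  na_new <- which(is.na(vals) & !is.na_like(raw[-1]), arr.ind = TRUE)
  if (nrow(na_new))
    stop(sprintf("non-numeric cell '%s' at sample '%s', feature '%s' in %s",
                 raw[na_new[1, 1], na_new[1, 2] + 1L],
                 sample_ids[na_new[1, 1]], feature_ids[na_new[1, 2]], path))
  block <- list(values = vals, kind = kind)
  class(block) <- "feature_block"
  check_kind_ranges(vals, rep(kind, ncol(vals))) # NA cells skipped here
  block
}

is.na_like <- function(df) {
  vapply(df, function(col) col %in% c("NA", "", "NaN"), logical(nrow(df)))
}

#' Write a feature block or dataset matrix as a tab-separated table
#'
#' Inverse of [load_feature_table()]: first column `sample_id`, header row of
#' feature ids. Full double precision is preserved so that a write/load
#' round-trip is the identity on the matrix.
#'
#' @param values numeric matrix with sample rownames and feature colnames,
#'   or a `feature_block`.
#' @param path output file path.
#' @export
write_feature_table <- function(values, path) {
  if (inherits(values, "feature_block")) values <- values$values
  df <- data.frame(sample_id = rownames(values),
                   format(values, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble feature blocks and clinical metadata into one dataset
#'
#' Column-concatenates methylation/expression/clinical blocks on the
#' intersection of their sample ids (samples missing from any block are
#' dropped with a warning), applies the missing-value policy, and attaches
#' survival columns from the clinical table.
#'
#' @param blocks list of `feature_block` objects from [load_feature_table()].
#' @param clinical data.frame with columns `sample_id`, `days_to_death`,
#'   `vital_status` (`"deceased"`/`"alive"` or 1/0), and optionally `age`,
#'   `gender`, `grade`.
#' @param na_action `"drop"` (default) removes features with any missing
#'   value before zero-variance filtering; `"impute"` replaces missing
#'   values with the per-feature median.
#' @return an [omics_dataset()].
#' @export
assemble_dataset <- function(blocks, clinical, na_action = c("drop", "impute")) {
  na_action <- match.arg(na_action)
  stopifnot(is.list(blocks), length(blocks) >= 1)
  clinical <- as.data.frame(clinical)
  req <- c("sample_id", "days_to_death", "vital_status")
  if (!all(req %in% colnames(clinical)))
    stop("clinical table must have columns: ", paste(req, collapse = ", "))

  ids <- Reduce(intersect, c(lapply(blocks, function(b) rownames(b$values)),
                             list(as.character(clinical$sample_id))))
  all_ids <- unique(c(unlist(lapply(blocks, function(b) rownames(b$values))),
                      as.character(clinical$sample_id)))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped))
    warning(length(dropped), " sample(s) absent from at least one block were dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  if (length(ids) == 0) stop("no samples shared by all blocks")

  mats <- lapply(blocks, function(b) b$values[ids, , drop = FALSE])
  values <- do.call(cbind, mats)
  feature_kind <- unlist(lapply(blocks, function(b) rep(b$kind, ncol(b$values))))

  if (anyNA(values)) {
    if (na_action == "drop") {
      keep <- !apply(is.na(values), 2, any)
      message(sum(!keep), " feature(s) with missing values dropped")
      values <- values[, keep, drop = FALSE]
      feature_kind <- feature_kind[keep]
    } else {
      values <- apply(values, 2, function(col) {
        col[is.na(col)] <- stats::median(col, na.rm = TRUE)
        col
      })
    }
  }

  rownames(clinical) <- as.character(clinical$sample_id)
  clin <- clinical[ids, , drop = FALSE]
  vs <- clin$vital_status
  event <- if (is.numeric(vs)) as.integer(vs != 0)
           else as.integer(tolower(as.character(vs)) %in% c("deceased", "dead", "1"))
  cov_cols <- intersect(c("age", "gender", "grade"), colnames(clin))
  covariates <- if (length(cov_cols)) clin[, cov_cols, drop = FALSE] else NULL

  omics_dataset(values, feature_kind,
                survival_days = clin$days_to_death, event = event,
                covariates = covariates)
}

#' Remove zero-variance features
#'
#' Drops every feature whose sample variance is exactly zero (constant
#' columns), preserving the order of the survivors — the first filtering
#' step applied to the assembled decision system.
#'
#' @param ds an [omics_dataset()].
#' @return the filtered dataset; errors if no feature would survive.
#' @export
drop_zero_variance <- function(ds) {
  stopifnot(inherits(ds, "omics_dataset"))
  v <- apply(ds$values, 2, stats::var)
  keep <- v > 0
  if (!any(keep)) stop("all features have zero variance")
  if (all(keep)) return(ds)
  ds$values <- ds$values[, keep, drop = FALSE]
  ds$feature_kind <- ds$feature_kind[keep]
  ds
}

#' Survival dichotomization rule
#'
#' Samples surviving up to `threshold_days` are labelled SHORT, those
#' surviving longer LONG. The default threshold of 400 days is the drop
#' point visible in glioma survival histograms (see
#' [survival_histogram_scan()]).
#'
#' @param threshold_days positive integer day threshold (default 400).
#' @param short_label,long_label class names.
#' @export
class_rule <- function(threshold_days = 400L, short_label = "SHORT",
                       long_label = "LONG") {
  threshold_days <- as.integer(threshold_days)
  if (length(threshold_days) != 1 || is.na(threshold_days) || threshold_days < 0)
    stop("`threshold_days` must be a single non-negative integer")
  structure(list(threshold_days = threshold_days,
                 short_label = short_label, long_label = long_label),
            class = "class_rule")
}

#' Assign the binary survival class
#'
#' Applies a [class_rule()] to `survival_days`: days <= threshold gives the
#' SHORT class, otherwise LONG. Requires an all-deceased cohort (`event`
#' all 1); censored samples cannot be dichotomized this way and belong only
#' in the Kaplan-Meier stage.
#'
#' @param ds an [omics_dataset()].
#' @param rule a [class_rule()].
#' @return the dataset with `class_label` set (factor, SHORT first).
#' @export
assign_classes <- function(ds, rule = class_rule()) {
  stopifnot(inherits(ds, "omics_dataset"), inherits(rule, "class_rule"))
  if (any(ds$event == 0L))
    stop("all samples must be deceased (event = 1) to assign survival classes; ",
         sum(ds$event == 0L), " censored sample(s) present")
  lab <- ifelse(ds$survival_days <= rule$threshold_days,
                rule$short_label, rule$long_label)
  ds$class_label <- factor(lab, levels = c(rule$short_label, rule$long_label))
  ds$class_rule <- rule
  message(sprintf("classes: %s = %d, %s = %d",
                  rule$short_label, sum(lab == rule$short_label),
                  rule$long_label, sum(lab == rule$long_label)))
  ds
}

#' Write / read a dataset bundle
#'
#' A bundle is a directory of plain TSV files (one per feature kind, one
#' clinical table) plus a manifest, the on-disk interchange format between
#' pipeline stages.
#'
#' @param ds an [omics_dataset()].
#' @param dir bundle directory (created if needed).
#' @return `dir`, invisibly (`write_dataset_bundle`); the restored
#'   [omics_dataset()] (`read_dataset_bundle`).
#' @export
write_dataset_bundle <- function(ds, dir) {
  stopifnot(inherits(ds, "omics_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (k in unique(ds$feature_kind)) {
    f <- file.path(dir, paste0(k, ".tsv"))
    write_feature_table(ds$values[, ds$feature_kind == k, drop = FALSE], f)
    files <- c(files, f)
  }
  clin <- data.frame(sample_id = rownames(ds$values),
                     days_to_death = ds$survival_days,
                     vital_status = ds$event)
  if (!is.null(ds$covariates)) clin <- cbind(clin, ds$covariates)
  cf <- file.path(dir, "samples.tsv")  # clinical metadata, not a feature block
  utils::write.table(clin, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, cf)
  manifest <- data.frame(file = basename(files), md5 = tools::md5sum(files))
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset_bundle
#' @param na_action forwarded to [assemble_dataset()].
#' @export
read_dataset_bundle <- function(dir, na_action = "drop") {
  kinds <- c("methylation", "expression", "clinical")
  blocks <- list()
  for (k in kinds) {
    f <- file.path(dir, paste0(k, ".tsv"))
    if (file.exists(f)) blocks[[k]] <- load_feature_table(f, k)
  }
  if (!length(blocks)) stop("no feature tables found in ", dir)
  clinical <- utils::read.table(file.path(dir, "samples.tsv"), header = TRUE,
                                sep = "\t", check.names = FALSE)
  assemble_dataset(blocks, clinical, na_action = na_action)
}
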