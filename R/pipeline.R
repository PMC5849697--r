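#' Pipeline run configuration
#'
#' One configuration object driving the whole analysis. Defaults are the
#' published full-scale settings (s = 50000, m = 500, t = 5, 400-day
#' dichotomy, beta strata 0.96/0.85, 25 bp flank, top-60 edges); desk-scale
#' runs override `mcfs`.
#'
#' @param data either a [synth_config()] (a synthetic cohort is generated)
#'   or a path to a dataset bundle directory (see
#'   [write_dataset_bundle()]).
#' @param class_rule a [class_rule()].
#' @param mcfs an [mcfs_config()].
#' @param n_perm,confidence permutation-cutoff settings (`n_perm = 0`
#'   disables the cutoff; the top `fallback_top` features are then used
#'   downstream).
#' @param fallback_top features taken from the top of the ranking when no
#'   cutoff is computed or nothing is significant (default 10).
#' @param top_edges number of ID-graph edges reported (default 60).
#' @param stats character subset of `c("mi", "kw", "corr", "ii")`.
#' @param validation `"cv"`, `"traintest"` or `"none"`; `"traintest"`
#'   requires a second bundle/config under `test_data`.
#' @param test_data optional test cohort (same forms as `data`).
#' @param classifiers classifier suite for validation.
#' @param strata a [strata_rule()] for the per-probe KM analysis.
#' @param flank region flank in bp (default 25).
#' @param annotations optional BED path(s) intersected with the methylated
#'   regions of the significant probes.
#' @param seed global integer seed, propagated to every stochastic stage.
#' @export
run_config <- function(data = synth_config(), class_rule = mcfsid::class_rule(),
                       mcfs = mcfs_config(), n_perm = 20L, confidence = 0.95,
                       fallback_top = 10L, top_edges = 60L,
                       stats = c("mi", "kw", "corr"),
                       validation = c("cv", "traintest", "none"),
                       test_data = NULL, classifiers = classifier_names(),
                       strata = strata_rule(), flank = 25L,
                       annotations = NULL, seed = 1L) {
  validation <- match.arg(validation)
  structure(list(data = data, class_rule = class_rule, mcfs = mcfs,
                 n_perm = as.integer(n_perm), confidence = confidence,
                 fallback_top = as.integer(fallback_top),
                 top_edges = as.integer(top_edges), stats = stats,
                 validation = validation, test_data = test_data,
                 classifiers = classifiers, strata = strata,
                 flank = as.integer(flank), annotations = annotations,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the [run_config()]
#' arguments (`synth`, `class_rule`, `mcfs`, ...) and builds the
#' corresponding configuration objects.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  data <- if (!is.null(y$synth)) do.call(synth_config, y$synth)
          else if (!is.null(y$bundle)) y$bundle
          else synth_config()
  run_config(
    data = data,
    class_rule = if (is.null(y$class_rule)) class_rule()
                 else do.call(class_rule, y$class_rule),
    mcfs = if (is.null(y$mcfs)) mcfs_config() else do.call(mcfs_config, y$mcfs),
    n_perm = y$n_perm %||% 20L, confidence = y$confidence %||% 0.95,
    fallback_top = y$fallback_top %||% 10L,
    top_edges = y$top_edges %||% 60L,
    stats = y$stats %||% c("mi", "kw", "corr"),
    validation = y$validation %||% "cv",
    test_data = if (!is.null(y$test_synth)) do.call(synth_config, y$test_synth)
                else y$test_bundle,
    strata = if (is.null(y$strata)) strata_rule()
             else do.call(strata_rule, y$strata),
    flank = y$flank %||% 25L, annotations = y$annotations,
    seed = y$seed %||% 1L)
}

load_stage_data <- function(data, rule, seed_offset = 0L) {
  if (inherits(data, "synth_config")) {
    sim <- generate_dataset(data)
    list(ds = sim$dataset, truth = sim$truth, probes = sim$probes)
  } else {
    ds <- read_dataset_bundle(data)
    ds <- drop_zero_variance(ds)
    ds <- assign_classes(ds, rule)
    list(ds = ds, truth = NULL, probes = NULL)
  }
}

write_stage <- function(obj, dir, file) {
  path <- file.path(dir, file)
  utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full MCFS-ID analysis pipeline
#'
#' Executes the stages in dependency order — load/generate, zero-variance
#' filtering, class assignment, MCFS-ID with permutation cutoff, ID-graph
#' edge ranking, dependency statistics, classifier validation, per-probe
#' Kaplan-Meier analysis of the top methylation feature, and (when
#' annotation BED tracks are given) methylated-region intersection —
#' writing each stage's table under `out_dir` plus a manifest of MD5
#' checksums. Reruns with an identical configuration reproduce identical
#' checksums. A stage failure aborts with the stage name; completed
#' outputs are kept.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  loaded <- stage("load", load_stage_data(cfg$data, cfg$class_rule))
  ds <- stage("filter", drop_zero_variance(loaded$ds))
  if (is.null(ds$class_label))
    ds <- stage("classes", assign_classes(ds, cfg$class_rule))
  cls_tab <- table(ds$class_label)
  outputs <- c(outputs, write_stage(
    data.frame(class = names(cls_tab), n = as.integer(cls_tab)),
    out_dir, "classes.tsv"))

  fit <- stage("mcfs", {
    set.seed(cfg$seed)
    mcfs(ds, cfg = cfg$mcfs,
         cutoff = if (cfg$n_perm >= 2) "permutation" else "none",
         n_perm = max(cfg$n_perm, 2L), confidence = cfg$confidence)
  })
  outputs <- c(outputs, write_stage(fit$ri, out_dir, "ri_ranking.tsv"))

  edges <- stage("idgraph", suppressWarnings(
    top_edges(fit$id_graph, cfg$top_edges)))
  outputs <- c(outputs, write_stage(edges, out_dir, "id_edges.tsv"))

  selected <- if (!is.null(fit$cutoff) && any(fit$ri$significant))
    significant_features(fit) else utils::head(fit$ri$feature, cfg$fallback_top)

  if ("mi" %in% cfg$stats) {
    mi <- stage("stats_mi",
                mi_significance(ds, features = selected, n_perm = 200L))
    outputs <- c(outputs, write_stage(mi, out_dir, "mi.tsv"))
  }
  if ("kw" %in% cfg$stats) {
    kw <- stage("stats_kw", kw_bonferroni(ds, features = selected))
    outputs <- c(outputs, write_stage(kw, out_dir, "kruskal_wallis.tsv"))
  }
  if ("corr" %in% cfg$stats) {
    cm <- stage("stats_corr", correlation_matrix(ds, features = selected))
    outputs <- c(outputs, write_stage(
      data.frame(feature = rownames(cm), cm, check.names = FALSE),
      out_dir, "correlation.tsv"))
  }
  if ("ii" %in% cfg$stats && !is.null(ds$covariates)) {
    ii_rows <- stage("stats_ii", do.call(rbind, lapply(selected, function(f) {
      res_age <- interaction_information(ds$values[, f],
                                         as.numeric(ds$covariates$age),
                                         ds$class_label)
      data.frame(feature = f, covariate = "age", ii = res_age$ii)
    })))
    outputs <- c(outputs, write_stage(ii_rows, out_dir, "interaction_info.tsv"))
  }

  if (cfg$validation != "none") {
    val <- stage("validate", {
      set.seed(cfg$seed + 1L)
      if (cfg$validation == "cv") {
        validate_features(ds, selected, mode = "cv",
                          classifiers = cfg$classifiers, seed = cfg$seed)
      } else {
        test <- load_stage_data(cfg$test_data, cfg$class_rule)$ds
        validate_features(ds, selected, mode = "traintest", test_ds = test,
                          classifiers = cfg$classifiers)
      }
    })
    outputs <- c(outputs, write_stage(val, out_dir, "validation.tsv"))
  }

  meth_sel <- selected[ds$feature_kind[selected] == "methylation"]
  km <- NULL
  if (length(meth_sel)) {
    km <- stage("survival", km_probe_analysis(ds, meth_sel[1], cfg$strata))
    outputs <- c(outputs, write_stage(km$curves, out_dir, "km_curves.tsv"))
    if (!is.null(km$logrank))
      outputs <- c(outputs, write_stage(
        data.frame(chisq = km$logrank$chisq, df = km$logrank$df,
                   p_value = km$logrank$p_value),
        out_dir, "logrank.tsv"))
  }

  if (!is.null(cfg$annotations) && !is.null(loaded$probes) && length(meth_sel)) {
    ov <- stage("regions", {
      regions <- make_regions(
        loaded$probes[loaded$probes$probe_id %in% meth_sel, , drop = FALSE],
        flank = cfg$flank)
      ann <- do.call(rbind, lapply(cfg$annotations, read_bed))
      intersect_regions(regions, ann)
    })
    outputs <- c(outputs, write_stage(ov, out_dir, "region_overlaps.tsv"))
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(seed = cfg$seed,
                        mcfs = cfg$mcfs[c("s", "m", "t", "u", "v")],
                        threshold_days = cfg$class_rule$threshold_days),
                   file.path(out_dir, "config_echo.yaml"))
  invisible(list(dataset = ds, fit = fit, selected = selected,
                 km = km, manifest = manifest))
}
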