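#' Pipeline configuration
#'
#' One serialisable object holding every tunable of the end-to-end analysis;
#' all defaults are the reference settings of the analysis (four gapped
#' bands, 6th-order zero-phase Butterworth, 10 s windows, six metrics,
#' alpha = 0.05 over 24 stage tests, 30 subject-wise 80/20 splits), with the
#' reduced hyperparameter grid as the default compute setting.
#'
#' @param n_subjects,segment_length_s,fs,n_channels,jitter_sd cohort
#'   settings, see [cohort_spec()].
#' @param window_s,edge_trim_s,filter_order preprocessing settings.
#' @param metrics connectivity metrics to analyse.
#' @param alpha nominal family-wise error rate for the stage statistics.
#' @param n_splits,test_n subject-wise split scheme.
#' @param grid_mode `"reduced"` or `"full"` hyperparameter grid.
#' @param classify_metrics metrics to run the classifier on (defaults to
#'   `metrics`; classification is the expensive stage).
#' @param include_power also run the band-power baseline classifier.
#' @param seed base seed for cohort, splits and learner.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(n_subjects = 14, segment_length_s = NULL, fs = 250,
                            n_channels = 30, jitter_sd = 0.1,
                            window_s = 10, edge_trim_s = 0, filter_order = 6,
                            metrics = metric_names(), alpha = 0.05,
                            n_splits = 30, test_n = 3,
                            grid_mode = "reduced",
                            classify_metrics = metrics,
                            include_power = FALSE, seed = 1) {
  bad <- setdiff(c(metrics, classify_metrics), metric_names())
  if (length(bad) > 0) {
    stop(sprintf("unknown metric name(s) in `metrics`: %s",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(n_subjects = n_subjects, segment_length_s = segment_length_s,
         fs = fs, n_channels = n_channels, jitter_sd = jitter_sd,
         window_s = window_s, edge_trim_s = edge_trim_s,
         filter_order = filter_order, metrics = metrics, alpha = alpha,
         n_splits = n_splits, test_n = test_n, grid_mode = grid_mode,
         classify_metrics = classify_metrics,
         include_power = include_power, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Save / load a pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns the
#'   reconstructed `pipeline_config` (round-trip identical).
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

#' Run the full pipeline: synthesis, connectivity, statistics, classification
#'
#' Generates the synthetic cohort defined by the config, computes the
#' connectivity (and optionally power) features, runs the Friedman/Nemenyi
#' stage-difference battery, classifies sleep stages per metric over the
#' subject-wise splits, writes all outputs under `out_dir` and returns a
#' manifest with MD5 hashes of every file. Reruns with the same config
#' produce identical outputs and hashes.
#'
#' Files written: `stage_statistics.csv`, `accuracies.csv` (split x metric),
#' `confusion_<metric>.csv`, `importances_<metric>.csv`, `summary.json`,
#' `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly: list with `config`, `package_version`,
#'   `seed`, `files` (named MD5 hashes), `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort_spec(n_subjects = config$n_subjects,
                      segment_length_s = config$segment_length_s,
                      fs = config$fs, n_channels = config$n_channels,
                      seed = config$seed, jitter_sd = config$jitter_sd)
  cohort <- generate_cohort(default_stage_profiles(), spec)
  fc <- cohort_features(cohort, metrics = config$metrics,
                        window_s = config$window_s,
                        edge_trim_s = config$edge_trim_s,
                        include_power = config$include_power)

  stats_tab <- stage_statistics(fc, alpha = config$alpha)
  utils::write.csv(stats_tab, file.path(out_dir, "stage_statistics.csv"),
                   row.names = FALSE)

  splits <- make_splits(unique(fc$meta$subject), n_splits = config$n_splits,
                        test_n = config$test_n, seed = config$seed)
  cfg <- classifier_config(grid_mode = config$grid_mode)
  targets <- config$classify_metrics
  if (config$include_power) targets <- c(targets, "power")
  agg <- list()
  acc <- matrix(NA_real_, config$n_splits, length(targets),
                dimnames = list(NULL, targets))
  for (m in targets) {
    runs <- run_classification(fc, metric = m, splits = splits,
                               config = cfg, seed = config$seed)
    agg[[m]] <- aggregate_runs(runs)
    acc[, m] <- agg[[m]]$accuracies
    utils::write.csv(as.data.frame(agg[[m]]$confusion),
                     file.path(out_dir, paste0("confusion_", m, ".csv")))
    utils::write.csv(
      data.frame(feature = names(agg[[m]]$importances),
                 importance = agg[[m]]$importances),
      file.path(out_dir, paste0("importances_", m, ".csv")),
      row.names = FALSE
    )
  }
  utils::write.csv(as.data.frame(acc), file.path(out_dir, "accuracies.csv"),
                   row.names = FALSE)

  summary <- list(
    n_recordings = length(cohort),
    n_epochs = nrow(fc$meta),
    n_features = ncol(fc$features[[1]]),
    alpha_adjusted = attr(stats_tab, "alpha_adjusted"),
    n_stage_tests = attr(stats_tab, "n_tests"),
    n_significant = sum(stats_tab$significant),
    mean_accuracy = lapply(agg, `[[`, "mean_accuracy"),
    band_share = lapply(agg, `[[`, "band_share")
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  save_config(config, file.path(out_dir, "config.json"))

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phasesleep")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(file.path(out_dir, "config.json"))),
    files = stats::setNames(unname(tools::md5sum(files)), basename(files)),
    summary = summary
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
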