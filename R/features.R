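#' Connectivity and power features for a whole cohort
#'
#' Runs the full preprocessing chain on every recording and computes, per
#' 10 s epoch, the connectivity feature vector of each requested metric
#' (band-major upper-triangle ordering, `4 * choose(n_channels, 2)`
#' coefficients; 1740 for 30 channels) and optionally the band-power
#' baseline features (`4 * n_channels`; 120 for 30 channels).
#'
#' @param cohort list of [eeg_recording()]s (e.g. from [generate_cohort()]).
#' @param metrics character vector, subset of [metric_names()].
#' @param bands band table, default [band_definitions()].
#' @param window_s epoch length in seconds.
#' @param edge_trim_s seconds trimmed from segment ends before epoching.
#' @param include_power also compute the power-feature baseline.
#' @return Object of class `fc_features`: list with `features` (named list,
#'   one epochs x n_feat matrix per metric), `power` (epochs x
#'   `4 * n_channels` matrix or `NULL`), `meta` (data frame with `subject`,
#'   `stage`, `epoch`), `band_names`, `n_channels`, `channel_names`.
#' @export
cohort_features <- function(cohort, metrics = metric_names(),
                            bands = band_definitions(), window_s = 10,
                            edge_trim_s = 0, include_power = TRUE) {
  metrics <- match.arg(metrics, metric_names(), several.ok = TRUE)
  rows <- lapply(cohort, function(rec) {
    pre <- preprocess_recording(rec, bands = bands, window_s = window_s,
                                edge_trim_s = edge_trim_s)
    n_ep <- length(pre[[1]])
    feat <- lapply(metrics, function(m) vector("list", n_ep))
    names(feat) <- metrics
    pow <- if (include_power) vector("list", n_ep) else NULL
    for (k in seq_len(n_ep)) {
      per_band <- lapply(pre, function(eps) eps[[k]])
      mats <- lapply(per_band, connectivity_matrices, metrics = metrics)
      for (m in metrics) {
        feat[[m]][[k]] <- vectorize_features(lapply(mats, `[[`, m),
                                             band_names = bands$name)
      }
      if (include_power) pow[[k]] <- power_features(per_band, bands$name)
    }
    list(
      feat = lapply(feat, function(fl) do.call(rbind, fl)),
      pow = if (include_power) do.call(rbind, pow) else NULL,
      meta = data.frame(subject = rec$subject_id, stage = rec$stage,
                        epoch = seq_len(n_ep), stringsAsFactors = FALSE)
    )
  })
  features <- lapply(metrics, function(m) {
    do.call(rbind, lapply(rows, function(r) r$feat[[m]]))
  })
  names(features) <- metrics
  out <- list(
    features = features,
    power = if (include_power) do.call(rbind, lapply(rows, `[[`, "pow")) else NULL,
    meta = do.call(rbind, c(lapply(rows, `[[`, "meta"), make.row.names = FALSE)),
    band_names = bands$name,
    n_channels = nrow(cohort[[1]]$data),
    channel_names = cohort[[1]]$channel_names
  )
  class(out) <- "fc_features"
  out
}

#' @export
print.fc_features <- function(x, ...) {
  cat(sprintf("<fc_features> %d epochs, %d subjects, metrics: %s (%d features each)\n",
              nrow(x$meta), length(unique(x$meta$subject)),
              paste(names(x$features), collapse = ", "),
              ncol(x$features[[1]])))
  invisible(x)
}

#' Subject-by-stage tables of band-averaged connectivity
#'
#' For one metric, averages the connectivity coefficients over all channel
#' pairs and all epochs of each subject's stage segment, separately per
#' band, yielding one subjects x stages table per band -- the input of the
#' Friedman stage-difference tests. Every (subject, stage) cell must have at
#' least one epoch (subjects with missing stages are not admitted).
#'
#' @param fc an `fc_features` object.
#' @param metric one of the metrics present in `fc`.
#' @return Named list (per band) of subjects x 4 matrices of class
#'   `subject_stage_table` with attributes `metric` and `band`.
#' @export
subject_stage_tables <- function(fc, metric) {
  stopifnot(inherits(fc, "fc_features"), metric %in% names(fc$features))
  X <- fc$features[[metric]]
  np <- choose(fc$n_channels, 2)
  subjects <- unique(fc$meta$subject)
  stages <- stage_levels()
  out <- lapply(seq_along(fc$band_names), function(b) {
    cols <- seq.int((b - 1) * np + 1, b * np)
    tab <- matrix(NA_real_, length(subjects), length(stages),
                  dimnames = list(subjects, stages))
    for (s in subjects) for (g in stages) {
      rows <- fc$meta$subject == s & fc$meta$stage == g
      if (!any(rows)) {
        stop(sprintf("no epochs for subject %s stage %s; incomplete subjects are excluded upstream", s, g))
      }
      tab[s, g] <- mean(X[rows, cols])
    }
    structure(tab, metric = metric, band = fc$band_names[b],
              class = c("subject_stage_table", "matrix"))
  })
  names(out) <- fc$band_names
  out
}
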