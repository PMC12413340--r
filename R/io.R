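# Plain-text exchange format for recordings: one CSV array (samples x
# channels) plus a JSON sidecar carrying subject, stage, sampling rate,
# channel names and the generating seed when known.

#' Write a recording as CSV + JSON sidecar
#'
#' @param rec an [eeg_recording()].
#' @param dir output directory (created if missing).
#' @param name file stem; default `<subject>_<stage>`.
#' @return Invisibly, the paths written (`csv`, `json`).
#' @export
write_recording <- function(rec, dir, name = NULL) {
  if (is.null(name)) name <- paste(rec$subject_id, rec$stage, sep = "_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  json <- file.path(dir, paste0(name, ".json"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, stage = rec$stage, fs = rec$fs,
         channel_names = rec$channel_names, seed = attr(rec, "seed")),
    json, auto_unbox = TRUE, digits = NA
  )
  invisible(list(csv = csv, json = json))
}

#' Read a recording written by [write_recording()]
#'
#' @param stem path without extension (both `<stem>.csv` and `<stem>.json`
#'   must exist).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  eeg_recording(t(as.matrix(df)), fs = meta$fs,
                channel_names = meta$channel_names,
                stage = meta$stage, subject_id = meta$subject_id)
}

#' Write a feature table as CSV
#'
#' One row per epoch: `subject`, `stage`, `epoch`, then the named feature
#' columns (`<band>_<ch_i>_<ch_j>` for connectivity, `<band>_<ch>` for
#' power), preserving the fixed band-major ordering.
#'
#' @param fc an `fc_features` object.
#' @param metric a metric in `fc`, or `"power"`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(fc, metric, path) {
  X <- if (identical(metric, "power")) fc$power else fc$features[[metric]]
  if (is.null(X)) stop(sprintf("no features for metric '%s'", metric))
  utils::write.csv(cbind(fc$meta, as.data.frame(X)), path, row.names = FALSE)
  invisible(path)
}
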