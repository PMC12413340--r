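#' Canonical EEG frequency bands with 1 Hz guard gaps
#'
#' Returns the four analysis bands: delta 1-3.5 Hz, theta 4.5-7 Hz, alpha
#' 8-12 Hz and beta 13-30 Hz. Adjacent bands are separated by gaps of at
#' least 1 Hz so that phase estimates near band edges do not overlap between
#' filters.
#'
#' @return A data frame with columns `name`, `low_hz`, `high_hz`, one row per
#'   band, ordered delta, theta, alpha, beta. This ordering is the band-major
#'   ordering used by [vectorize_features()] and [power_features()].
#' @export
#' @examples
#' band_definitions()
band_definitions <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta"),
    low_hz = c(1, 4.5, 8, 13),
    high_hz = c(3.5, 7, 12, 30),
    stringsAsFactors = FALSE
  )
}

#' Validate a band-definition table
#'
#' Checks the invariants the pipeline relies on: positive edges with
#' `low < high`, bands sorted by frequency, and gaps of at least 1 Hz
#' between adjacent bands.
#'
#' @param bands data frame as returned by [band_definitions()].
#' @param min_gap_hz minimum separation between adjacent bands (Hz).
#' @return `bands`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_bands <- function(bands, min_gap_hz = 1) {
  stopifnot(is.data.frame(bands), all(c("name", "low_hz", "high_hz") %in% names(bands)))
  if (any(bands$low_hz <= 0) || any(bands$low_hz >= bands$high_hz)) {
    stop("each band must satisfy 0 < low_hz < high_hz")
  }
  if (nrow(bands) > 1) {
    o <- order(bands$low_hz)
    gaps <- bands$low_hz[o][-1] - bands$high_hz[o][-nrow(bands)]
    if (any(gaps < min_gap_hz)) {
      stop(sprintf("adjacent bands must be separated by >= %g Hz", min_gap_hz))
    }
  }
  invisible(bands)
}

#' Fixed AASM stage labels used throughout the package
#' @return Character vector `c("W", "N1", "N2", "N3")` (wakefulness and the
#'   three NREM stages); this ordering is used for confusion-matrix rows and
#'   stage columns everywhere.
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3")
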