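#' Construct an EEG recording object
#'
#' A lightweight container for one continuous, single-stage EEG segment:
#' a channels x time matrix plus sampling rate and labels.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param stage AASM stage label, one of [stage_levels()], or `NA`.
#' @param subject_id subject identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL,
                          stage = NA_character_, subject_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("`data` must be a finite numeric matrix (channels x time)")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("length(channel_names) must equal nrow(data)")
  }
  if (!is.na(stage) && !stage %in% stage_levels()) {
    stop(sprintf("unknown stage label '%s'; expected one of %s",
                 stage, paste(stage_levels(), collapse = ", ")))
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         stage = stage, subject_id = as.character(subject_id)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, stage %s: %d channels x %.1f s @ %g Hz\n",
              x$subject_id, x$stage, nrow(x$data), ncol(x$data) / x$fs, x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return Numeric scalar, seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that the per-sample channel mean of the output is zero. Idempotent.
#'
#' @param rec an `eeg_recording` with at least two channels.
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2) stop("average reference requires >= 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

# Cached zero-phase Butterworth design. `order` is the final band-pass filter
# order; signal::butter() doubles the order for a pass-band specification, so
# the design call uses order/2.
design_bandpass <- function(low_hz, high_hz, fs, order = 6) {
  if (high_hz >= fs / 2) stop("band edge at or above Nyquist frequency")
  if (low_hz <= 0 || low_hz >= high_hz) stop("invalid band edges")
  if (order %% 2 != 0) stop("band-pass filter order must be even")
  signal::butter(order / 2, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a 6th-order digital Butterworth band-pass,
#' applied forward and backward (`signal::filtfilt`) so that the output has
#' zero phase distortion and the effective magnitude response is the squared
#' one-pass response.
#'
#' @param rec an `eeg_recording`.
#' @param band one row of [band_definitions()] (or any list with `name`,
#'   `low_hz`, `high_hz`).
#' @param order final band-pass filter order (default 6).
#' @return The band-limited `eeg_recording`, with attribute `"band"` set to
#'   the band name.
#' @export
bandpass <- function(rec, band, order = 6) {
  if (rec$fs <= 2 * band$high_hz) {
    stop(sprintf("fs = %g Hz too low for band %s (%g-%g Hz)",
                 rec$fs, band$name, band$low_hz, band$high_hz))
  }
  filt <- design_bandpass(band$low_hz, band$high_hz, rec$fs, order)
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(filt, x)))
  rownames(rec$data) <- rec$channel_names
  attr(rec, "band") <- band$name
  rec
}

#' Analytic signal of a real vector
#'
#' FFT construction of `x + i * Hilbert(x)`: the negative-frequency half of
#' the spectrum is zeroed and the positive half doubled, so the modulus is
#' the instantaneous amplitude and the argument the instantaneous phase
#' (positive-frequency convention).
#'
#' @param x numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous amplitude and phase of a band-limited recording
#'
#' Applies [analytic_signal()] to every channel of the full continuous
#' segment (before epoching, to keep edge transients out of the interior)
#' and returns amplitude `A(t) = |x + i x_H|` and phase
#' `phi(t) = arg(x + i x_H)` wrapped to (-pi, pi].
#'
#' @param rec a band-limited `eeg_recording` (output of [bandpass()]).
#' @return List with elements `amplitude` and `phase` (channels x time
#'   matrices), plus `fs`, `band`, `stage`, `subject_id` carried over.
#' @export
analytic <- function(rec) {
  Z <- t(apply(rec$data, 1, analytic_signal))
  out <- list(
    amplitude = abs(Z), phase = Arg(Z),
    fs = rec$fs, band = attr(rec, "band"),
    channel_names = rec$channel_names,
    stage = rec$stage, subject_id = rec$subject_id
  )
  rownames(out$amplitude) <- rownames(out$phase) <- rec$channel_names
  class(out) <- "analytic_series"
  out
}

#' Cut an analytic series into non-overlapping epochs
#'
#' Splits the continuous amplitude/phase arrays into consecutive windows of
#' `window_s` seconds. A trailing partial window is discarded, so a segment
#' of duration `D` yields `floor(D / window_s)` epochs. Optionally the first
#' and last `edge_trim_s` seconds are removed beforehand to drop filter and
#' Hilbert transients (default 0 so that window counts equal the printed
#' duration/10 bookkeeping).
#'
#' @param series an `analytic_series` from [analytic()].
#' @param window_s epoch length in seconds (default 10).
#' @param edge_trim_s seconds removed from each end before epoching.
#' @return List of `analytic_epoch` objects, each with `amplitude`, `phase`
#'   (channels x window samples), `band`, `epoch_index`, `stage`,
#'   `subject_id`, `fs`.
#' @export
epoch_analytic <- function(series, window_s = 10, edge_trim_s = 0) {
  fs <- series$fs
  n <- ncol(series$amplitude)
  trim <- round(edge_trim_s * fs)
  keep <- seq.int(trim + 1, n - trim)
  if (length(keep) < window_s * fs) {
    stop(sprintf("segment of %.1f s (after trimming) is shorter than one %g s window",
                 length(keep) / fs, window_s))
  }
  wlen <- round(window_s * fs)
  n_ep <- floor(length(keep) / wlen)
  lapply(seq_len(n_ep), function(k) {
    idx <- keep[seq.int((k - 1) * wlen + 1, k * wlen)]
    structure(
      list(amplitude = series$amplitude[, idx, drop = FALSE],
           phase = series$phase[, idx, drop = FALSE],
           band = series$band, epoch_index = k, fs = fs,
           channel_names = series$channel_names,
           stage = series$stage, subject_id = series$subject_id),
      class = "analytic_epoch"
    )
  })
}

#' Full per-recording preprocessing: reference, filter, Hilbert, epoch
#'
#' Convenience wrapper running [average_reference()], then per band
#' [bandpass()], [analytic()] and [epoch_analytic()]. All bands of one
#' recording therefore share the same epoch grid.
#'
#' @param rec an `eeg_recording`.
#' @param bands band table, default [band_definitions()].
#' @param window_s epoch length in seconds.
#' @param edge_trim_s seconds trimmed from each segment end before epoching.
#' @param filter_order Butterworth band-pass order.
#' @return Named list (one element per band) of lists of `analytic_epoch`.
#' @export
preprocess_recording <- function(rec, bands = band_definitions(), window_s = 10,
                                 edge_trim_s = 0, filter_order = 6) {
  validate_bands(bands)
  rec <- average_reference(rec)
  out <- lapply(seq_len(nrow(bands)), function(b) {
    epoch_analytic(analytic(bandpass(rec, bands[b, ], order = filter_order)),
                   window_s = window_s, edge_trim_s = edge_trim_s)
  })
  names(out) <- bands$name
  out
}
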