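# Synthetic NREM sleep EEG with stage- and band-dependent phase coupling.
#
# Each stage profile mixes, per frequency band, one narrowband common source
# (band-passed Gaussian noise, so coupling is graded rather than saturating
# as it would be for pure sinusoids) into all channels through zero-lag,
# distance-decaying spatial weights -- a volume-conduction surrogate -- with
# an optional per-channel phase lag, on top of independent 1/f background
# noise. N2 additionally receives transient spindle-band bursts.

run_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Scalp focus of each band's common source (schematic montage coordinates):
# delta frontal, theta fronto-central, alpha occipital, beta central.
band_source_xy <- function() {
  list(delta = c(0, 0.8), theta = c(0, 0.5), alpha = c(0, -0.9), beta = c(0, 0))
}

#' Stage profile for the synthetic generator
#'
#' Describes one AASM stage: per-band mixing weight of the band's common
#' source into the channels (`coupling_strength`, in \[0, 1\]), per-band,
#' per-channel source phase lags in radians (`source_lag`; `NULL` selects
#' the default distance-proportional lag gradient of `lag_scale` radians per
#' unit scalp distance from the band's source focus), the spindle-band burst
#' rate in events per minute (nonzero only for N2 in the defaults) and the
#' background 1/f noise standard deviation.
#'
#' @param stage one of [stage_levels()].
#' @param coupling_strength named numeric vector over all four bands, each in
#'   \[0, 1\].
#' @param source_lag `NULL`, or named list band -> numeric lag vector
#'   (radians, one per channel).
#' @param burst_rate spindle bursts per minute, `>= 0`.
#' @param noise_sd background noise SD (arbitrary units; sources have unit SD).
#' @param lag_scale radians of source lag per unit scalp distance when
#'   `source_lag` is `NULL`.
#' @return Object of class `stage_profile`.
#' @export
stage_profile <- function(stage, coupling_strength, source_lag = NULL,
                          burst_rate = 0, noise_sd = 1, lag_scale = 0.8) {
  if (!stage %in% stage_levels()) {
    stop(sprintf("invalid stage label '%s'", stage))
  }
  bands <- band_definitions()$name
  if (!all(bands %in% names(coupling_strength))) {
    stop("coupling_strength must name all four bands")
  }
  coupling_strength <- coupling_strength[bands]
  if (any(coupling_strength < 0 | coupling_strength > 1)) {
    stop("coupling_strength values must lie in [0, 1]")
  }
  if (burst_rate < 0) stop("burst_rate must be >= 0")
  structure(
    list(stage = stage, coupling_strength = coupling_strength,
         source_lag = source_lag, burst_rate = burst_rate,
         noise_sd = noise_sd, lag_scale = lag_scale),
    class = "stage_profile"
  )
}

#' Default stage profiles
#'
#' The package's reference study conditions: alpha coupling strongest in
#' wakefulness and fading through N1/N2 into N3; delta coupling rising as
#' sleep deepens; moderate theta coupling peaking in N1; spindle-band bursts
#' (6/min) in N2 only. Magnitudes are mixing weights relative to unit-SD
#' sources over unit-SD 1/f noise.
#'
#' @param noise_sd background noise SD applied to every stage.
#' @return Named list of [stage_profile()] objects (`W`, `N1`, `N2`, `N3`).
#' @export
default_stage_profiles <- function(noise_sd = 1) {
  cs <- function(delta, theta, alpha, beta) {
    c(delta = delta, theta = theta, alpha = alpha, beta = beta)
  }
  list(
    W  = stage_profile("W",  cs(0.10, 0.15, 0.80, 0.20), noise_sd = noise_sd),
    N1 = stage_profile("N1", cs(0.20, 0.35, 0.45, 0.15), noise_sd = noise_sd),
    N2 = stage_profile("N2", cs(0.50, 0.25, 0.25, 0.30), noise_sd = noise_sd,
                       burst_rate = 6),
    N3 = stage_profile("N3", cs(0.80, 0.20, 0.15, 0.10), noise_sd = noise_sd)
  )
}

#' High-contrast stage profiles
#'
#' A strongly stage-separated, low-noise condition: each stage is dominated
#' by a different band (W alpha, N1 theta, N2 spindle-band beta plus rising
#' delta, N3 delta) over weak background noise. Used to probe the upper end
#' of classifier performance, where stage labels should be recovered almost
#' perfectly.
#'
#' @param noise_sd background noise SD (default 0.3).
#' @return Named list of [stage_profile()] objects.
#' @export
high_contrast_profiles <- function(noise_sd = 0.3) {
  cs <- function(delta, theta, alpha, beta) {
    c(delta = delta, theta = theta, alpha = alpha, beta = beta)
  }
  list(
    W  = stage_profile("W",  cs(0.05, 0.10, 0.90, 0.10), noise_sd = noise_sd),
    N1 = stage_profile("N1", cs(0.15, 0.60, 0.45, 0.10), noise_sd = noise_sd),
    N2 = stage_profile("N2", cs(0.45, 0.20, 0.20, 0.70), noise_sd = noise_sd,
                       burst_rate = 10),
    N3 = stage_profile("N3", cs(0.90, 0.10, 0.05, 0.05), noise_sd = noise_sd)
  )
}

#' Per-stage segment lengths of the reference cohort
#'
#' The 14 x 4 table of segment durations (seconds) for the reference cohort
#' of 14 subjects, one artifact-free segment per NREM stage each (minimum
#' 100 s, grand total 11376 s). Used as the default `segment_length_s` of
#' [cohort_spec()] when `n_subjects = 14`.
#'
#' @return 14 x 4 numeric matrix, columns `W`, `N1`, `N2`, `N3`.
#' @export
reference_segment_lengths <- function() {
  m <- matrix(c(
    180, 188, 183, 181,
    183, 123, 182, 181,
    210, 210, 210, 210,
    120, 120, 120, 120,
    270, 270, 270, 270,
    300, 300, 300, 300,
    181, 185, 183, 180,
    120, 120, 120, 120,
    270, 270, 270, 270,
    240, 240, 240, 240,
    150, 150, 150, 150,
    150, 150, 150, 150,
    300, 300, 300, 300,
    184, 180, 181, 181
  ), ncol = 4, byrow = TRUE)
  dimnames(m) <- list(paste0("s", 1:14), stage_levels())
  m
}

#' Cohort specification for the synthetic generator
#'
#' @param n_subjects number of subjects (default 14).
#' @param segment_length_s seconds of data per stage segment: `NULL` (use
#'   [reference_segment_lengths()] when `n_subjects = 14`, otherwise a
#'   constant 200 s), a scalar, or an `n_subjects` x 4 matrix. Every segment
#'   must be at least 100 s.
#' @param fs sampling rate in Hz (default 250; must exceed twice the highest
#'   band edge, 30 Hz).
#' @param n_channels channel count (default 30, the shipped montage).
#' @param seed base RNG seed; all per-recording seeds are derived from it.
#' @param jitter_sd SD of the truncated-normal multiplicative inter-subject
#'   jitter on coupling strengths (default 0.1, i.e. 10% of strength).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 14, segment_length_s = NULL, fs = 250,
                        n_channels = 30, seed = 1, jitter_sd = 0.1) {
  if (fs <= 60) stop("fs must exceed twice the highest band edge (30 Hz)")
  if (is.null(segment_length_s)) {
    segment_length_s <- if (n_subjects == 14) reference_segment_lengths() else 200
  }
  if (is.matrix(segment_length_s)) {
    stopifnot(nrow(segment_length_s) == n_subjects, ncol(segment_length_s) == 4)
    seg <- segment_length_s
  } else {
    seg <- matrix(segment_length_s, n_subjects, 4)
  }
  colnames(seg) <- stage_levels()
  if (any(seg < 100)) stop("segment_length_s must be >= 100 s per segment")
  structure(
    list(n_subjects = n_subjects, segment_length_s = seg, fs = fs,
         n_channels = n_channels, seed = as.integer(seed),
         jitter_sd = jitter_sd),
    class = "cohort_spec"
  )
}

# 1/f-amplitude-shaped Gaussian noise of length n, unit SD.
pink_noise <- function(n) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))          # avoid the DC singularity
  f <- pmin(f, n - f + 1)            # mirror for negative frequencies
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE) / n)
  (x - mean(x)) / sd(x)
}

# For reduced channel counts take an evenly spaced (hence spatially spread)
# subset of the 30-channel montage, not the first n rows (which would all be
# frontal and nearly cancel under the average reference).
montage_for <- function(n_channels) {
  mon <- default_montage()
  if (n_channels == nrow(mon)) return(mon)
  if (n_channels < nrow(mon)) {
    return(mon[round(seq(1, nrow(mon), length.out = n_channels)), , drop = FALSE])
  }
  stop(sprintf("n_channels > %d not supported by the shipped montage", nrow(mon)))
}

mixing_weights <- function(mon, src_xy, sigma = 0.6) {
  d2 <- (mon$x - src_xy[1])^2 + (mon$y - src_xy[2])^2
  exp(-d2 / (2 * sigma^2))
}

#' Generate one labelled synthetic EEG segment
#'
#' Builds, per band, a narrowband common source (white noise band-passed
#' with the analysis filter, unit SD) and mixes it into every channel with
#' zero-lag distance-decaying weights times `coupling_strength[band]`,
#' phase-rotated by the per-channel source lag; adds independent 1/f noise
#' of SD `noise_sd` per channel; for profiles with `burst_rate > 0` adds
#' 1 s Hann-windowed 14 Hz bursts from a common central source. Output is
#' deterministic given `seed`.
#'
#' @param profile a [stage_profile()].
#' @param spec a [cohort_spec()].
#' @param subject_id subject label.
#' @param seed integer RNG seed for this recording.
#' @param duration_s segment length in seconds; defaults to the `spec` entry
#'   for subject 1 and the profile's stage.
#' @return An [eeg_recording()].
#' @export
generate_stage_recording <- function(profile, spec, subject_id = "s1",
                                     seed = spec$seed, duration_s = NULL) {
  stopifnot(inherits(profile, "stage_profile"), inherits(spec, "cohort_spec"))
  if (is.null(duration_s)) duration_s <- spec$segment_length_s[1, profile$stage]
  fs <- spec$fs
  n <- round(duration_s * fs)
  nch <- spec$n_channels
  mon <- montage_for(nch)
  bands <- band_definitions()
  src_xy <- band_source_xy()

  run_with_seed(seed, {
    data <- matrix(0, nch, n)
    for (b in seq_len(nrow(bands))) {
      bname <- bands$name[b]
      strength <- profile$coupling_strength[[bname]]
      if (strength == 0) next
      filt <- design_bandpass(bands$low_hz[b], bands$high_hz[b], fs)
      src <- signal::filtfilt(filt, rnorm(n))
      a <- analytic_signal(src)
      a <- a / sd(Re(a))
      w <- mixing_weights(mon, src_xy[[bname]])
      lag <- if (!is.null(profile$source_lag)) {
        profile$source_lag[[bname]]
      } else {
        profile$lag_scale * sqrt((mon$x - src_xy[[bname]][1])^2 +
                                 (mon$y - src_xy[[bname]][2])^2)
      }
      data <- data + strength * (w * Re(exp(1i * lag) %o% a))
    }
    if (profile$noise_sd > 0) {
      for (ch in seq_len(nch)) {
        data[ch, ] <- data[ch, ] + profile$noise_sd * pink_noise(n)
      }
    }
    if (profile$burst_rate > 0) {
      n_burst <- rpois(1, profile$burst_rate * duration_s / 60)
      if (n_burst > 0) {
        w <- mixing_weights(mon, src_xy$beta)
        lag <- profile$lag_scale * sqrt(mon$x^2 + mon$y^2)
        blen <- round(fs)               # 1 s bursts
        win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = blen)))
        tt <- seq_len(blen) / fs
        for (k in seq_len(n_burst)) {
          onset <- sample.int(n - blen, 1)
          g <- win * exp(1i * (2 * pi * 14 * tt + runif(1, 0, 2 * pi)))
          seg <- seq.int(onset, onset + blen - 1)
          data[, seg] <- data[, seg] + 2 * (w * Re(exp(1i * lag) %o% g))
        }
      }
    }
    eeg_recording(data, fs, channel_names = mon$name,
                  stage = profile$stage, subject_id = subject_id)
  })
}

jitter_factor <- function(n, sd) {
  f <- 1 + rnorm(n, 0, sd)
  pmin(pmax(f, 0), 2)                  # truncate to [0, 2]
}

#' Generate a full synthetic cohort
#'
#' One recording per subject and stage (`n_subjects x 4`). Coupling
#' strengths receive a per-subject, per-band multiplicative truncated-normal
#' jitter (SD `spec$jitter_sd`, shared across that subject's stages) so that
#' subject-wise train/test splits face genuine between-subject variance.
#' Per-recording seeds are derived reproducibly from `spec$seed`; the same
#' spec yields a bit-identical cohort.
#'
#' @param profiles named list of [stage_profile()]s for all of
#'   [stage_levels()]; default [default_stage_profiles()].
#' @param spec a [cohort_spec()].
#' @return List of [eeg_recording()]s named `<subject>_<stage>`, with the
#'   spec attached as attribute `"spec"`.
#' @export
generate_cohort <- function(profiles = default_stage_profiles(), spec = cohort_spec()) {
  stopifnot(all(stage_levels() %in% names(profiles)))
  bands <- band_definitions()$name
  base <- spec$seed %% 200000L
  jit <- run_with_seed(spec$seed, {
    matrix(jitter_factor(spec$n_subjects * length(bands), spec$jitter_sd),
           spec$n_subjects, length(bands), dimnames = list(NULL, bands))
  })
  out <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- paste0("s", s)
    for (g in seq_along(stage_levels())) {
      stg <- stage_levels()[g]
      prof <- profiles[[stg]]
      prof$coupling_strength <- pmin(pmax(prof$coupling_strength * jit[s, ], 0), 1)
      seed_sg <- base * 10000L + (s - 1L) * 4L + g
      out[[paste(sid, stg, sep = "_")]] <- generate_stage_recording(
        prof, spec, subject_id = sid, seed = seed_sg,
        duration_s = spec$segment_length_s[s, stg]
      )
    }
  }
  attr(out, "spec") <- spec
  out
}
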