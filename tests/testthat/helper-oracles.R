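# Shared oracles and cached fixtures for the test suite. Oracles are
# deliberately independent re-derivations (periodogram-based coherence,
# explicit rank arithmetic, direct formula evaluation), never calls into the
# code paths they check.

# --- constructed cross-spectra -------------------------------------------

# Epoch with a prescribed phase-difference series (channel j has phase 0).
make_css <- function(dphi, amp_i = rep(1, length(dphi)), amp_j = amp_i) {
  cross_spectrum(amp_i, amp_j, phase_i = dphi, phase_j = rep(0, length(dphi)))
}

# Two-channel analytic_epoch with given amplitude/phase rows.
make_epoch <- function(amp, phase, band = "alpha", fs = 250,
                       stage = "W", subject = "s1") {
  structure(
    list(amplitude = amp, phase = phase, band = band, epoch_index = 1L,
         fs = fs, channel_names = rownames(amp) %||% paste0("ch", seq_len(nrow(amp))),
         stage = stage, subject_id = subject),
    class = "analytic_epoch"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random analytic epoch from independent band-limited noise channels.
random_epoch <- function(n_channels, fs = 250, dur_s = 10,
                         band = band_definitions()[3, ], seed = 1) {
  rec <- run_with_seed_test(seed, {
    eeg_recording(matrix(rnorm(n_channels * fs * dur_s), n_channels), fs)
  })
  series <- analytic(bandpass(rec, band))
  epoch_analytic(series)[[1]]
}

run_with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# --- frequency-domain coherence oracle -----------------------------------

# Smoothed-periodogram magnitude coherence averaged over a band, via
# stats::spec.pgram on the raw (unfiltered) bivariate series.
welch_band_coherence <- function(x, y, fs, low, high, spans = c(31, 31)) {
  sp <- stats::spec.pgram(stats::ts(cbind(x, y), frequency = fs),
                          spans = spans, taper = 0.1, detrend = TRUE,
                          plot = FALSE)
  sel <- sp$freq >= low & sp$freq <= high
  mean(sqrt(sp$coh[sel]))
}

# --- brute-force Friedman oracle -----------------------------------------

# Explicit rank arithmetic: per-row average ranks computed by counting,
# column rank sums, the chi-square form and the tie correction, all written
# out longhand.
brute_force_friedman <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  R <- matrix(0, n, k)
  ties_term <- 0
  for (r in seq_len(n)) {
    row <- tab[r, ]
    for (c in seq_len(k)) {
      # average rank by direct counting
      R[r, c] <- sum(row < row[c]) + (sum(row == row[c]) + 1) / 2
    }
    for (v in unique(row)) {
      tt <- sum(row == v)
      ties_term <- ties_term + tt^3 - tt
    }
  }
  Rj <- colSums(R)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  corr <- 1 - ties_term / (n * (k^3 - k))
  if (corr <= 0) return(list(statistic = 0, p = 1))
  stat <- stat / corr
  list(statistic = stat, p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

# Nemenyi studentized-range p for one pair, from first principles.
brute_force_nemenyi_pair <- function(tab, a, b) {
  n <- nrow(tab); k <- ncol(tab)
  R <- t(apply(tab, 1, rank))
  q <- abs(mean(R[, a]) - mean(R[, b])) / sqrt(k * (k + 1) / (6 * n))
  stats::ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
}

# --- null-measurement-chain oracle ---------------------------------------

# 1/f-amplitude noise built here independently of the package generator.
oracle_pink <- function(n) {
  spec_amp <- c(0, 1 / sqrt(seq_len(floor(n / 2))))
  phases <- runif(length(spec_amp), 0, 2 * pi)
  half <- spec_amp * exp(1i * phases)
  full <- c(half, Conj(rev(half[2:(n - length(half) + 1)])))[1:n]
  x <- Re(stats::fft(full, inverse = TRUE))
  (x - mean(x)) / stats::sd(x)
}

# One epoch of the full measurement chain applied to INDEPENDENT channels:
# 1/f noise -> average reference -> band-pass -> Hilbert -> first window.
# This is the null against which generator couplings are compared; the
# average reference itself induces a small common-mode correlation that the
# null must share.
null_chain_pairmean <- function(n_channels, seed, metric = "PLV",
                                band = band_definitions()[3, ], dur_s = 12) {
  ep <- run_with_seed_test(seed, {
    x <- t(vapply(seq_len(n_channels), function(i) oracle_pink(250 * dur_s),
                  numeric(250 * dur_s)))
    rec <- average_reference(eeg_recording(x, 250))
    epoch_analytic(analytic(bandpass(rec, band)))[[1]]
  })
  M <- connectivity_matrix(ep, metric)
  mean(M[upper.tri(M)])
}

# --- cached heavy fixtures -----------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# High-contrast small cohort + features, reused by several classification
# tests (8 subjects, 10 channels, 100 s segments).
contrast_features <- function() {
  cached_fixture("contrast_fc", {
    spec <- cohort_spec(n_subjects = 8, segment_length_s = 100,
                        n_channels = 10, seed = 21)
    cohort <- generate_cohort(high_contrast_profiles(), spec)
    cohort_features(cohort, metrics = c("COH", "PLV"))
  })
}
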