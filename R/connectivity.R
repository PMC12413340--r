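#' Cross-spectrum time series for one channel pair
#'
#' Builds the per-sample complex cross-spectrum
#' `S_ij(t) = A_i(t) A_j(t) exp(+i (phi_i(t) - phi_j(t)))` and the power
#' series `S_ii = A_i^2`, `S_jj = A_j^2` for one epoch. The sign convention
#' (`+i (phi_i - phi_j)`) fixes the sign of iCOH: a positive phase lead of
#' channel i over channel j at a quarter cycle gives iCOH = +1.
#'
#' Samples where either amplitude is exactly zero have an undefined phase
#' difference; they are flagged and excluded from the phase-only metrics
#' (PLV, ciPLV, PLI, wPLI), with the exclusion count recorded.
#'
#' @param amp_i,amp_j nonnegative amplitude vectors `A(t)`.
#' @param phase_i,phase_j phase vectors in radians.
#' @return Object of class `cross_spectrum`: list with complex `S_ij`, real
#'   `S_ii`, `S_jj`, `dphi` (= phi_i - phi_j), logical `valid` (nonzero
#'   amplitude on both channels) and `n_excluded`.
#' @export
cross_spectrum <- function(amp_i, amp_j, phase_i, phase_j) {
  stopifnot(length(amp_i) == length(amp_j),
            length(amp_i) == length(phase_i),
            length(amp_i) == length(phase_j))
  if (any(amp_i < 0) || any(amp_j < 0)) stop("amplitudes must be nonnegative")
  dphi <- phase_i - phase_j
  valid <- amp_i > 0 & amp_j > 0
  structure(
    list(S_ij = amp_i * amp_j * exp(1i * dphi),
         S_ii = amp_i^2, S_jj = amp_j^2,
         dphi = dphi, valid = valid,
         n_excluded = sum(!valid)),
    class = "cross_spectrum"
  )
}

#' Coherence of one epoch
#'
#' `COH = |<S_ij>| / sqrt(<S_ii><S_jj>)`, the magnitude of the
#' amplitude-weighted mean phasor normalised by the channel powers. All
#' angle brackets are time averages over the epoch. Sensitive to amplitude
#' covariation and to zero-lag (volume-conduction) coupling. Bounded in
#' \[0, 1\].
#'
#' @param css a [cross_spectrum()].
#' @return Numeric scalar; `NaN` with a warning if a channel has zero power.
#' @export
coh <- function(css) {
  denom <- sqrt(mean(css$S_ii) * mean(css$S_jj))
  if (denom == 0) {
    warning("zero-power channel: COH undefined")
    return(NaN)
  }
  abs(mean(css$S_ij)) / denom
}

#' Imaginary part of coherency of one epoch
#'
#' `iCOH = Im(<S_ij> / sqrt(<S_ii><S_jj>))`. Instantaneous (zero-lag)
#' coupling is purely real and contributes nothing, which makes iCOH
#' insensitive to volume conduction; it retains amplitude sensitivity.
#' Bounded in \[-1, 1\]; the sign follows the `+i (phi_i - phi_j)`
#' cross-spectrum convention of [cross_spectrum()].
#'
#' @inheritParams coh
#' @return Numeric scalar in \[-1, 1\].
#' @export
icoh <- function(css) {
  denom <- sqrt(mean(css$S_ii) * mean(css$S_jj))
  if (denom == 0) {
    warning("zero-power channel: iCOH undefined")
    return(NaN)
  }
  Im(mean(css$S_ij)) / denom
}

# Phase-only metrics share the valid-sample mask; epochs dominated by
# zero-amplitude samples are the caller's responsibility (see
# `max_excluded_frac` in connectivity_matrix()).
phasor <- function(css) exp(1i * css$dphi[css$valid])

#' Phase-locking value of one epoch
#'
#' `PLV = |<exp(i dphi)>|`: the resultant length of the unit phasors of the
#' phase difference. 1 for a constant phase difference, ~N^(-1/2) for
#' incoherent phases. Amplitude-agnostic but sensitive to zero-lag coupling.
#'
#' @inheritParams coh
#' @return Numeric scalar in \[0, 1\].
#' @export
plv <- function(css) abs(mean(phasor(css)))

#' Corrected imaginary phase-locking value of one epoch
#'
#' `ciPLV = |<Im exp(i dphi)>| / sqrt(1 - <Re exp(i dphi)>^2)`: the lagged
#' part of the mean unit phasor, renormalised by the zero-lag part, so
#' purely instantaneous coupling scores 0 while a consistent quarter-cycle
#' lag scores 1. When the real part saturates (`|<Re>| = 1`, the noise-free
#' zero-lag limit) the ratio is defined as 0 and flagged via attribute
#' `"degenerate"`.
#'
#' @inheritParams coh
#' @return Numeric scalar in \[0, 1\].
#' @export
ciplv <- function(css) {
  u <- phasor(css)
  re <- mean(Re(u))
  den2 <- 1 - re^2
  if (den2 <= .Machine$double.eps) {
    return(structure(0, degenerate = TRUE))
  }
  abs(mean(Im(u))) / sqrt(den2)
}

#' Phase lag index of one epoch
#'
#' `PLI = |<sign(Im S_ij)>|`: the asymmetry of the lag/lead sign
#' distribution, with `sign(0) = 0`. Ignores both amplitude and the size of
#' the lag; noise around zero lag flips signs at random, which wPLI
#' down-weights.
#'
#' @inheritParams coh
#' @return Numeric scalar in \[0, 1\].
#' @export
pli <- function(css) abs(mean(sign(Im(css$S_ij[css$valid]))))

#' Weighted phase lag index of one epoch
#'
#' `wPLI = |<Im S_ij>| / <|Im S_ij|>`: sign consistency of the imaginary
#' cross-spectrum weighted by its magnitude, so samples near zero lag carry
#' little weight. A purely real cross-spectrum (zero denominator) is defined
#' as 0 and flagged via attribute `"degenerate"`.
#'
#' @inheritParams coh
#' @return Numeric scalar in \[0, 1\].
#' @export
wpli <- function(css) {
  im <- Im(css$S_ij[css$valid])
  den <- mean(abs(im))
  if (den == 0) return(structure(0, degenerate = TRUE))
  abs(mean(im)) / den
}

#' Names of the six supported coupling metrics
#' @return `c("COH", "iCOH", "PLV", "ciPLV", "PLI", "wPLI")`.
#' @export
metric_names <- function() c("COH", "iCOH", "PLV", "ciPLV", "PLI", "wPLI")

# Row-major upper-triangle pair index (i < j): (1,2), (1,3), ..., (n-1,n).
pair_index <- function(n) combn(seq_len(n), 2)

#' All-pairs connectivity matrices for one epoch
#'
#' Computes one or more coupling metrics for every unordered channel pair of
#' an epoch in a single vectorised pass and returns symmetric channels x
#' channels matrices with `NA` on the diagonal (self-coupling is undefined).
#' For iCOH the stored value is the signed i<j value mirrored symmetrically
#' (the i<j orientation is the documented convention; magnitude metrics are
#' orientation-free).
#'
#' Epochs in which more than `max_excluded_frac` of samples have zero
#' amplitude on any channel are rejected, since phase-difference statistics
#' on the remainder are unreliable.
#'
#' @param epoch an `analytic_epoch` from [epoch_analytic()].
#' @param metrics character vector, subset of [metric_names()].
#' @param max_excluded_frac maximum tolerated fraction of zero-amplitude
#'   samples per channel (default 0.01).
#' @return Named list of matrices, one per requested metric, each with
#'   attributes `metric`, `band`, `epoch_index`, `stage`, `subject_id`.
#' @export
connectivity_matrices <- function(epoch, metrics = metric_names(),
                                  max_excluded_frac = 0.01) {
  metrics <- match.arg(metrics, metric_names(), several.ok = TRUE)
  A <- epoch$amplitude
  P <- epoch$phase
  nch <- nrow(A)
  if (nch < 2) stop("need >= 2 channels")
  zero_frac <- rowMeans(A == 0)
  if (any(zero_frac > max_excluded_frac)) {
    stop(sprintf("epoch rejected: %d channel(s) exceed %.1f%% zero-amplitude samples",
                 sum(zero_frac > max_excluded_frac), 100 * max_excluded_frac))
  }
  pr <- pair_index(nch)
  i <- pr[1, ]; j <- pr[2, ]
  X <- A * cos(P); Y <- A * sin(P)
  # S_ij(t) = z_i conj(z_j): Re = X_i X_j + Y_i Y_j, Im = Y_i X_j - X_i Y_j
  ReS <- X[i, , drop = FALSE] * X[j, , drop = FALSE] +
         Y[i, , drop = FALSE] * Y[j, , drop = FALSE]
  ImS <- Y[i, , drop = FALSE] * X[j, , drop = FALSE] -
         X[i, , drop = FALSE] * Y[j, , drop = FALSE]
  pw <- rowMeans(A^2)
  dphi <- P[i, , drop = FALSE] - P[j, , drop = FALSE]

  vals <- list()
  if (any(c("COH", "iCOH") %in% metrics)) {
    norm <- sqrt(pw[i] * pw[j])
    mRe <- rowMeans(ReS); mIm <- rowMeans(ImS)
    if ("COH" %in% metrics) vals$COH <- sqrt(mRe^2 + mIm^2) / norm
    if ("iCOH" %in% metrics) vals$iCOH <- mIm / norm
  }
  if (any(c("PLV", "ciPLV") %in% metrics)) {
    mCos <- rowMeans(cos(dphi)); mSin <- rowMeans(sin(dphi))
    if ("PLV" %in% metrics) vals$PLV <- sqrt(mCos^2 + mSin^2)
    if ("ciPLV" %in% metrics) {
      den2 <- pmax(1 - mCos^2, 0)
      vals$ciPLV <- ifelse(den2 <= .Machine$double.eps, 0, abs(mSin) / sqrt(den2))
    }
  }
  if ("PLI" %in% metrics) vals$PLI <- abs(rowMeans(sign(ImS)))
  if ("wPLI" %in% metrics) {
    den <- rowMeans(abs(ImS))
    vals$wPLI <- ifelse(den == 0, 0, abs(rowMeans(ImS)) / den)
  }

  out <- lapply(metrics, function(m) {
    M <- matrix(NA_real_, nch, nch,
                dimnames = list(epoch$channel_names, epoch$channel_names))
    M[cbind(i, j)] <- vals[[m]]
    M[cbind(j, i)] <- vals[[m]]
    structure(M, metric = m, band = epoch$band,
              epoch_index = epoch$epoch_index,
              stage = epoch$stage, subject_id = epoch$subject_id)
  })
  names(out) <- metrics
  out
}

#' Connectivity matrix for a single metric
#'
#' @inheritParams connectivity_matrices
#' @param metric one of [metric_names()].
#' @return A symmetric channels x channels matrix (see
#'   [connectivity_matrices()]).
#' @export
connectivity_matrix <- function(epoch, metric, max_excluded_frac = 0.01) {
  connectivity_matrices(epoch, metrics = metric,
                        max_excluded_frac = max_excluded_frac)[[1]]
}

#' Flatten per-band connectivity matrices into one feature vector
#'
#' Fixed ordering: band-major (delta, theta, alpha, beta), and within each
#' band the upper-triangle pairs (i, j), i < j, in row-major order. For 30
#' channels this yields 4 x 435 = 1740 coefficients. Feature names are
#' `<band>_<ch_i>_<ch_j>` so importances remain comparable across runs.
#'
#' @param matrices named list of connectivity matrices, one per band, in
#'   [band_definitions()] order, all same metric and epoch.
#' @param band_names expected band names (default the four canonical bands).
#' @return Named numeric vector of length `n_bands * choose(n_channels, 2)`.
#' @export
vectorize_features <- function(matrices, band_names = band_definitions()$name) {
  if (!all(band_names %in% names(matrices))) {
    stop(sprintf("missing band(s): %s",
                 paste(setdiff(band_names, names(matrices)), collapse = ", ")))
  }
  out <- lapply(band_names, function(b) {
    M <- matrices[[b]]
    pr <- pair_index(nrow(M))
    v <- M[cbind(pr[1, ], pr[2, ])]
    names(v) <- paste(b, rownames(M)[pr[1, ]], rownames(M)[pr[2, ]], sep = "_")
    v
  })
  unlist(out)
}

#' Rebuild per-band matrices from a feature vector
#'
#' Inverse of [vectorize_features()] on the upper triangle (the diagonal is
#' restored as `NA`).
#'
#' @param v feature vector from [vectorize_features()].
#' @param n_channels channel count of the original matrices.
#' @param band_names band names, in order.
#' @param channel_names optional channel labels for dimnames.
#' @return Named list of symmetric matrices, one per band.
#' @export
devectorize_features <- function(v, n_channels,
                                 band_names = band_definitions()$name,
                                 channel_names = NULL) {
  np <- choose(n_channels, 2)
  stopifnot(length(v) == np * length(band_names))
  pr <- pair_index(n_channels)
  out <- lapply(seq_along(band_names), function(b) {
    M <- matrix(NA_real_, n_channels, n_channels,
                dimnames = list(channel_names, channel_names))
    vb <- v[seq.int((b - 1) * np + 1, b * np)]
    M[cbind(pr[1, ], pr[2, ])] <- vb
    M[cbind(pr[2, ], pr[1, ])] <- vb
    M
  })
  names(out) <- band_names
  out
}

#' Band power features for one epoch set
#'
#' Per channel and band, the epoch mean of the squared analytic amplitude
#' `<A(t)^2>` (so a unit-amplitude in-band sinusoid scores 1 under this
#' definition). Ordering is band-major then channel; 30 channels x 4 bands
#' gives 120 features. These are the spectral-power baseline features for
#' the classifier comparison.
#'
#' @param epochs_by_band named list (one `analytic_epoch` per band, same
#'   epoch index) as produced by indexing [preprocess_recording()] output.
#' @param band_names expected band names, in order.
#' @return Named numeric vector of length `n_bands * n_channels`.
#' @export
power_features <- function(epochs_by_band, band_names = band_definitions()$name) {
  if (!all(band_names %in% names(epochs_by_band))) {
    stop(sprintf("missing band(s): %s",
                 paste(setdiff(band_names, names(epochs_by_band)), collapse = ", ")))
  }
  out <- lapply(band_names, function(b) {
    ep <- epochs_by_band[[b]]
    v <- rowMeans(ep$amplitude^2)
    names(v) <- paste(b, ep$channel_names, sep = "_")
    v
  })
  unlist(out)
}
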