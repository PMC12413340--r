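test_that("metrics take their exact analytic values on constructed phase configurations", {
  n <- 1000
  # constant quarter-cycle lag, unit amplitudes
  css_q <- make_css(rep(pi / 2, n))
  expect_equal(coh(css_q), 1)
  expect_equal(icoh(css_q), 1)
  expect_equal(plv(css_q), 1)
  expect_equal(ciplv(css_q), 1, ignore_attr = TRUE)
  expect_equal(pli(css_q), 1)
  expect_equal(wpli(css_q), 1, ignore_attr = TRUE)

  # zero lag: magnitude metrics saturate, lag-based metrics vanish
  css_0 <- make_css(rep(0, n))
  expect_equal(coh(css_0), 1)
  expect_equal(icoh(css_0), 0)
  expect_equal(plv(css_0), 1)
  expect_equal(ciplv(css_0), 0, ignore_attr = TRUE)
  expect_true(isTRUE(attr(ciplv(css_0), "degenerate")))
  expect_equal(pli(css_0), 0)          # sign(0) = 0 convention
  expect_equal(wpli(css_0), 0, ignore_attr = TRUE)
  expect_true(isTRUE(attr(wpli(css_0), "degenerate")))

  # antiphase: coherency is real and negative
  css_pi <- make_css(rep(pi, n))
  expect_equal(icoh(css_pi), 0, tolerance = 1e-12)
  expect_equal(plv(css_pi), 1)
  expect_equal(coh(css_pi), 1)

  # phasor cancellation: equal counts on the four quadrant angles
  css_u <- make_css(rep(c(0, pi / 2, pi, 3 * pi / 2), each = 25))
  expect_equal(plv(css_u), 0, tolerance = 1e-12)

  # constant lag of any value gives PLV 1
  css_a <- make_css(rep(1.234, n))
  expect_equal(plv(css_a), 1)
})

test_that("PLI counts lag signs and wPLI weights them by magnitude", {
  # 70% at +pi/4, 30% at -pi/4 -> |0.7 - 0.3| = 0.4
  css <- make_css(c(rep(pi / 4, 70), rep(-pi / 4, 30)))
  expect_equal(pli(css), 0.4)

  # Im(S) values {+2, -1, -1}: signed mean cancels, wPLI = 0
  amp_i <- c(sqrt(2), 1, 1); amp_j <- c(sqrt(2), 1, 1)
  css2 <- cross_spectrum(amp_i, amp_j,
                         phase_i = c(pi / 2, -pi / 2, -pi / 2),
                         phase_j = c(0, 0, 0))
  expect_equal(Im(css2$S_ij), c(2, -1, -1))
  expect_equal(wpli(css2), 0, ignore_attr = TRUE)

  # consistent positive lags, varying amplitude -> wPLI = 1
  css3 <- make_css(runif(200, 0.2, 1.5), amp_i = runif(200, 0.5, 2))
  expect_equal(wpli(css3), 1, ignore_attr = TRUE)
})

test_that("PLV on incoherent phases matches the Rayleigh small-sample expectation", {
  # E[PLV] for N iid uniform phases = sqrt(pi)/2 * N^(-1/2)
  N <- 400
  vals <- run_with_seed_test(11, {
    replicate(500, plv(make_css(runif(N, -pi, pi))))
  })
  expect_equal(mean(vals), sqrt(pi) / 2 / sqrt(N), tolerance = 0.05)
})

test_that("ciPLV matches a direct evaluation of its formula on a noisy lag sample", {
  dphi <- run_with_seed_test(12, pi / 2 + rnorm(2500, 0, 0.1))
  oracle <- abs(mean(sin(dphi))) / sqrt(1 - mean(cos(dphi))^2)
  expect_equal(ciplv(make_css(dphi)), oracle, ignore_attr = TRUE)
  expect_gt(oracle, 0.9)   # near-quarter-cycle lag scores high
})

test_that("wPLI resists noise pushing samples across the zero-lag border", {
  # a true small positive lag buried in symmetric phase noise: many samples
  # cross zero lag, flipping PLI signs at random, while wPLI down-weights
  # exactly those samples -- so wPLI detects the lag more strongly and with
  # lower relative variability
  stats <- run_with_seed_test(13, {
    replicate(400, {
      css <- make_css(0.03 + rnorm(500, 0, 0.05))
      c(pli = pli(css), wpli = as.numeric(wpli(css)))
    })
  })
  m <- rowMeans(stats)
  cv <- sqrt(apply(stats, 1, stats::var)) / m
  expect_gt(m["wpli"], m["pli"])
  expect_lt(cv["wpli"], cv["pli"])
})

test_that("zero-power channels are flagged undefined", {
  css <- cross_spectrum(rep(0, 10), rep(1, 10), rep(0, 10), rep(0, 10))
  expect_warning(v <- coh(css), "zero-power")
  expect_true(is.nan(v))
  expect_equal(css$n_excluded, 10)
})

test_that("connectivity matrices are symmetric with the right pair count", {
  ep30 <- random_epoch(30, seed = 31)
  M <- connectivity_matrix(ep30, "PLV")
  expect_equal(dim(M), c(30, 30))
  expect_equal(sum(!is.na(M[upper.tri(M)])), 435)
  expect_equal(M, t(M))
  expect_true(all(is.na(diag(M))))

  ep3 <- random_epoch(3, seed = 32)
  M3 <- connectivity_matrix(ep3, "COH")
  expect_equal(sum(!is.na(M3[upper.tri(M3)])), 3)

  # permutation equivariance
  ep5 <- random_epoch(5, seed = 33)
  perm <- c(4, 2, 5, 1, 3)
  ep5p <- ep5
  ep5p$amplitude <- ep5$amplitude[perm, ]
  ep5p$phase <- ep5$phase[perm, ]
  ep5p$channel_names <- ep5$channel_names[perm]
  for (m in metric_names()) {
    M_p <- connectivity_matrix(ep5p, m)
    M_ref <- connectivity_matrix(ep5, m)[perm, perm]
    if (m == "iCOH") {
      # iCOH is antisymmetric in the pair orientation; the stored i<j
      # convention makes equivariance hold up to sign
      expect_equal(abs(M_p), abs(M_ref), ignore_attr = TRUE, tolerance = 1e-12)
    } else {
      expect_equal(M_p, M_ref, ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("fast all-pairs path agrees with the scalar per-pair metrics", {
  ep <- random_epoch(6, seed = 34)
  mats <- connectivity_matrices(ep)
  for (i in 1:5) for (j in (i + 1):6) {
    css <- cross_spectrum(ep$amplitude[i, ], ep$amplitude[j, ],
                          ep$phase[i, ], ep$phase[j, ])
    expect_equal(mats$COH[i, j], coh(css), tolerance = 1e-10)
    expect_equal(mats$iCOH[i, j], icoh(css), tolerance = 1e-10)
    expect_equal(mats$PLV[i, j], plv(css), tolerance = 1e-10)
    expect_equal(mats$ciPLV[i, j], ciplv(css), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(mats$PLI[i, j], pli(css), tolerance = 1e-10)
    expect_equal(mats$wPLI[i, j], wpli(css), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("metric bounds and the iCOH/COH envelope hold on random epochs", {
  for (seed in 41:44) {
    ep <- random_epoch(5, seed = seed, band = band_definitions()[seed %% 4 + 1, ])
    mats <- connectivity_matrices(ep)
    ut <- upper.tri(mats$COH)
    for (m in c("COH", "PLV", "ciPLV", "PLI", "wPLI")) {
      expect_true(all(mats[[m]][ut] >= 0 & mats[[m]][ut] <= 1 + 1e-12))
    }
    expect_true(all(abs(mats$iCOH[ut]) <= mats$COH[ut] + 1e-12))
  }
})

test_that("PLV equals COH when amplitudes are constant in time", {
  n <- 2000
  phase <- rbind(run_with_seed_test(45, cumsum(rnorm(n, 0.1, 0.05))),
                 run_with_seed_test(46, cumsum(rnorm(n, 0.1, 0.05))))
  phase <- (phase + pi) %% (2 * pi) - pi
  amp <- matrix(c(2, 0.5), 2, n)       # constant per channel
  ep <- make_epoch(amp, phase)
  mats <- connectivity_matrices(ep, c("COH", "PLV"))
  expect_equal(mats$COH[1, 2], mats$PLV[1, 2], tolerance = 1e-12)
})

test_that("all six metrics are exactly invariant to positive channel rescaling", {
  ep <- random_epoch(4, seed = 47)
  scaled <- ep
  scaled$amplitude[2, ] <- 3.7 * ep$amplitude[2, ]
  base <- connectivity_matrices(ep)
  resc <- connectivity_matrices(scaled)
  for (m in metric_names()) {
    expect_equal(resc[[m]], base[[m]], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("epochs with too many zero-amplitude samples are rejected", {
  ep <- random_epoch(3, seed = 48)
  ep$amplitude[1, 1:100] <- 0
  expect_error(connectivity_matrices(ep), "zero-amplitude")
})

test_that("feature vectors use fixed band-major upper-triangle ordering", {
  mk_mats <- function(nch, seed) {
    out <- lapply(seq_len(4), function(b) {
      M <- run_with_seed_test(seed + b, matrix(runif(nch^2), nch))
      M[lower.tri(M)] <- t(M)[lower.tri(M)]
      diag(M) <- NA
      rownames(M) <- colnames(M) <- paste0("ch", seq_len(nch))
      M
    })
    names(out) <- band_definitions()$name
    out
  }
  mats30 <- mk_mats(30, 100)
  v <- vectorize_features(mats30)
  expect_length(v, 1740)
  expect_equal(unname(v[1]), mats30$delta[1, 2])
  expect_equal(unname(v[2]), mats30$delta[1, 3])   # row-major pairs
  expect_equal(unname(v[436]), mats30$theta[1, 2]) # band-major blocks
  expect_match(names(v)[1], "^delta_")

  expect_length(vectorize_features(mk_mats(3, 200)), 12)
  expect_error(vectorize_features(mats30[1:3]), "missing band")

  # round trip restores the upper triangle
  back <- devectorize_features(v, 30, channel_names = rownames(mats30$delta))
  for (b in names(mats30)) {
    expect_equal(back[[b]][upper.tri(back[[b]])],
                 mats30[[b]][upper.tri(mats30[[b]])])
  }
})

test_that("power features measure mean squared analytic amplitude per channel and band", {
  fs <- 250
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 10 * t)
  x <- rbind(tone, -tone)                   # average-reference invariant pair
  pre <- preprocess_recording(eeg_recording(x, fs))
  pf <- power_features(lapply(pre, `[[`, 2))  # interior epoch
  expect_length(pf, 8)                        # 2 channels x 4 bands
  # unit sinusoid: analytic amplitude 1, so <A^2> ~ 1 under this definition
  expect_equal(unname(pf["alpha_ch1"]), 1, tolerance = 0.07)
  expect_lt(pf["delta_ch1"], 0.01)

  # zero signal scores exactly zero power
  zero_eps <- lapply(band_definitions()$name, function(b) {
    make_epoch(matrix(0, 2, 100), matrix(0, 2, 100), band = b)
  })
  names(zero_eps) <- band_definitions()$name
  expect_true(all(power_features(zero_eps) == 0))

  ep30 <- lapply(band_definitions()$name, function(b) random_epoch(30, seed = 55))
  names(ep30) <- band_definitions()$name
  expect_length(power_features(ep30), 120)
})
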