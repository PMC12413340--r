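---
title: "Phase-coupling connectivity and sleep-stage classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-coupling connectivity and sleep-stage classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phasesleep)
```

This vignette is the package's own account of its methods: the measurement
model, the statistical and classification procedures, the synthetic data
the tests rely on, and the numerical and design choices made where several
defensible options existed.

## Measurement model

The pipeline treats one continuous, artifact-free, single-stage EEG segment
(30 channels, 250 Hz, average reference) as the unit of input. Processing
is strictly sequential:

1. **Average reference.** The instantaneous mean over channels is
   subtracted, so signals sum to zero at every sample. This is idempotent
   and matches the referencing of the recordings the analysis targets.
2. **Band-pass filtering** into delta (1–3.5 Hz), theta (4.5–7 Hz), alpha
   (8–12 Hz) and beta (13–30 Hz). Adjacent bands are separated by at least
   1 Hz so that phase estimates near an edge are not shared between two
   filters. The filter is a digital Butterworth band-pass of final order 6,
   applied forward and backward (`signal::filtfilt`), so the output is
   zero-phase and the effective magnitude response is the squared one-pass
   response. We read "6th order" as the order of the resulting band-pass
   (a 3rd-order prototype per edge); the often-quoted 25 dB/octave slope is
   not an exact property of any Butterworth order and is treated as
   descriptive. Measured on the installed filters, a 10 Hz tone leaks
   through the delta band at < 1% RMS after the forward–backward pass.
3. **Analytic signal** per channel on the *whole* segment, before any
   epoching, so filter and Hilbert transients exist only at segment ends
   rather than at every window boundary. The construction zeroes the
   negative-frequency half of the FFT and doubles the positive half;
   amplitude is the modulus, phase the argument wrapped to (−π, π], and
   `A·cos(φ)` reconstructs the band-passed signal to numerical precision.
4. **Epoching** into non-overlapping 10 s windows; a trailing partial
   window is discarded, so a segment of `D` seconds yields `floor(D/10)`
   epochs. An `edge_trim_s` argument can drop the first and last seconds
   before epoching; its default is 0 so that window counts equal the
   printed `duration/10` bookkeeping of the reference cohort (a 120 s
   segment yields 12 windows). For real recordings with visible filter
   transients a 2 s trim is a reasonable setting; for the stationary
   synthetic segments the transient is negligible relative to a 10 s
   window.

All six coupling metrics are computed in the time domain from the
per-sample cross-spectrum `S_ij(t) = A_i A_j exp(+i(φ_i − φ_j))` and its
epoch averages. Two conventions deserve note:

* **Cross-spectrum sign.** We fix `S_ij = A_i A_j e^{+iΔφ}` with
  `Δφ = φ_i − φ_j` and the analytic signal defined with the
  positive-frequency convention. Only the *sign* of iCOH depends on this
  choice (a quarter-cycle lead of channel *i* gives iCOH = +1); every
  magnitude-based metric is unaffected.
* **Degenerate denominators.** `sign(0) = 0` in PLI; the 0/0 cases of wPLI
  (purely real cross-spectrum) and ciPLV (`|⟨Re e^{iΔφ}⟩| = 1`) are defined
  as 0 and flagged with a `degenerate` attribute. This is the continuous
  limit from the noise-free zero-lag case, where the lag-based metrics
  should read "no lagged coupling". Note that an exactly antiphase signal
  pair sits on the `sign(0)` boundary only in exact arithmetic; floating
  point places `sin(π) ≈ 1e−16` infinitesimally off zero, which is why the
  tests pin the sign-based metrics at zero lag rather than at antiphase.
* **Zero-amplitude samples** have undefined phase; they are excluded from
  the phase-only metrics with a recorded count, and an epoch in which any
  channel exceeds 1% zero-amplitude samples is rejected outright.

In feature vectors the **signed** iCOH value of the `i < j` orientation is
retained (information-preserving; the classifier can use the sign), while
stage-level summaries work with means over pairs like every other metric.
Feature ordering is fixed and named — band-major (delta, theta, alpha,
beta), upper-triangle pairs row-major within band, names
`<band>_<ch_i>_<ch_j>` — so importances are comparable across runs. For 30
channels: 4 × 435 = 1740 connectivity features, and 4 × 30 = 120 band-power
features (`⟨A²⟩` per channel and band) for the power baseline.

## Stage statistics

One FC parameter per subject, stage and band — the grand mean over all
channel pairs and all epochs of that subject's stage segment — forms a
subjects × 4 table per metric and band. Because coupling coefficients are
bounded and skewed, a Shapiro–Wilk screen is run once per parameter and the
analysis proceeds nonparametrically: a Friedman rank test per metric × band
family, Bonferroni-controlled over the 24 families (α = 0.05/24 ≈ 0.00208),
with Nemenyi post-hoc pairwise stage comparisons computed only where the
omnibus test is significant.

The Friedman statistic is implemented directly (average ranks within
subjects, chi-square form, k − 1 degrees of freedom) *with* the standard
tie correction `1 − Σ(t³−t)/(n(k³−k))`, mirroring the scientific Python
implementation commonly used for this test; `stats::friedman.test`, which
omits the correction, serves as an independent cross-check on tie-free
tables in the test suite. The Nemenyi p-values come from the studentized
range distribution (`stats::ptukey` at infinite df), not from a critical
value table, avoiding interpolation drift.

**Type-I calibration.** The battery's false-positive behaviour is verified
on 200 null cohorts in which the subjects × stages tables are i.i.d. draws
with no stage effect. The tables are simulated directly rather than through
full EEG synthesis: the Friedman test consumes *only* the subject-level
table, so this calibration is exact for the statistic while running in
seconds. The zero-coupling behaviour of the full synthesis-to-connectivity
chain is verified separately against a measurement-chain null oracle (see
below).

## Classification

One gradient-boosted tree classifier per metric, trained on per-epoch
feature vectors with the AASM label as target. The learner is an
off-the-shelf gradient-boosted decision-tree ensemble (the `xgboost`
implementation, single-threaded and without row/column subsampling, making
runs bit-reproducible for a fixed seed); its internals are deliberately not
part of this package's contribution. Importances are normalised gain
shares.

* **Outer splits:** 30 distinct subject-wise 80/20 partitions (11 train / 3
  test of 14 subjects), sampled uniformly *without replacement* from the
  364 possible test sets. Whether the reference analysis sampled with or
  without replacement is unstated; without replacement guarantees the
  splits are distinct, which is the property the scheme exists to provide.
* **Inner CV:** the hyperparameter grid (learning rate ∈ {0.005, 0.01,
  0.05, 0.1, 0.15}, trees ∈ {250, …, 1500}, depth ∈ {3, …, 7}; 150
  combinations) is scored by 5-fold cross-validation with *subject-grouped*
  folds: no subject contributes epochs to both sides of a fold. Grouping is
  our choice (the reference description is silent); epoch-level folds would
  leak within-subject autocorrelation and inflate CV scores, and grouping
  is consistent with the subject-wise outer design.
* **Tie-breaking** in the grid is toward the cheapest adequate model:
  smaller ensemble, then shallower trees, then smaller learning rate.
* **Reduced grid.** The default compute setting evaluates a fixed
  3-combination subset of the full grid. The full 150-point grid is opt-in:
  it costs ~50× more and, on the well-separated synthetic cohorts, selects
  models indistinguishable in test accuracy.
* **No class weighting:** stage segments have near-equal durations by
  construction, so chance level is 0.25 and reweighting is unnecessary.

Accuracies across the six metrics are compared with one-way ANOVA plus
Tukey HSD, on the 30 × 6 table of per-split accuracies.

## The synthetic cohort generator

No sleep EEG is distributed with the package, so the generator must supply
data whose *statistical structure* matches what the analysis assumes. Per
stage and band it builds a narrowband common source — white noise passed
through the band's own analysis filter, normalised to unit SD — and mixes
it into every channel with zero-lag, distance-decaying weights
(`exp(−d²/2σ²)`, σ = 0.6 in schematic head coordinates) from a band-specific
scalp focus (delta frontal, theta fronto-central, alpha occipital, beta
central), phase-rotated by a per-channel lag that grows with distance from
the focus (0.8 rad per unit distance by default). On top of this sit
independent 1/f-spectrum noise channels (unit SD by default) and, for N2,
1 s Hann-windowed 14 Hz bursts (6/min) from a common central source.

Why these choices:

* **Stochastic sources, not sinusoids.** Band-passed noise gives graded,
  imperfect coupling; deterministic sinusoids would saturate every metric
  at 1 and hide implementation errors.
* **Zero-lag mixing** is the volume-conduction surrogate: it produces the
  instantaneous correlations that separate COH/PLV from the lag-based
  metrics, the central discrimination the metric family exists for.
* **Distance-proportional lags** give the lag-based metrics something real
  to detect: channels near the source couple almost instantaneously,
  distant channels with a consistent phase offset. A pure zero-lag world
  would make iCOH/ciPLV/PLI/wPLI blind to every stage contrast.
* **Stage profiles** encode the qualitative physiology: alpha coupling
  strongest in W and fading through N1/N2 into N3 (0.80/0.45/0.25/0.15
  mixing weight), delta coupling rising with sleep depth
  (0.10/0.20/0.50/0.80), moderate theta peaking in N1, and spindle-band
  bursts only in N2. The numbers are fixed reference conditions chosen once
  to give clearly graded but non-saturated coupling over unit background
  noise; they are not fitted to any empirical dataset.
* **Inter-subject variability:** each subject's coupling strengths are
  multiplied by a truncated-normal factor (SD 10%, shared across that
  subject's stages) so subject-wise splits face genuine between-subject
  variance.
* **Montage.** The reference analysis does not list its 30-channel montage;
  we declare a fixed 30-label subset of the 10-10 system (a standard
  32-electrode MR-compatible cap minus the two non-EEG channels) with
  schematic 2-D positions used only for the mixing geometry. Reduced
  channel counts take an evenly spaced subset so that small test montages
  remain spatially spread — an all-frontal subset would see its common
  sources nearly cancelled by the average reference.
* **Reference segment lengths.** The default 14-subject cohort uses the
  reference per-subject segment durations (100–300 s, 11376 s in total,
  1134 ten-second windows); other cohort sizes default to 200 s segments.
  Segments shorter than 100 s are rejected, matching the inclusion rule of
  the reference cohort.

What the generator does **not** emulate: realistic K-complex or vertex-wave
morphology, non-stationarity within a segment, EOG/EMG contamination,
biophysical head geometry, and any sleep-stage structure beyond band-wise
phase coupling and power. Consequently, passing tests demonstrate that the
*pipeline* recovers the coupling structure it is designed to measure — they
are not evidence about classification accuracy on clinical EEG, where the
reported accuracies of comparable analyses are far below the near-perfect
values reached on high-contrast synthetic cohorts.

A seeded null oracle closes the loop: with all couplings at zero, the
pair-mean of every metric matches the distribution obtained by pushing
*independent* 1/f channels through the same measurement chain (average
reference included — referencing alone induces a small common-mode
correlation of order −1/(n−1) that a naive independent-channel null would
miss).

## Determinism and problem sizes

Every stochastic step — cohort synthesis, subject jitter, split sampling,
CV fold assignment, the learner — derives its seed from a single base seed;
identical configurations reproduce bit-identical cohorts, features and
accuracies. Derived seeds stay below 2³¹.

The shipped test suite and the acceptance script use deliberately scaled
problem sizes chosen to exercise every code path at full fidelity while
keeping a complete run in minutes on one CPU: cohorts of 4–8 subjects with
6–12 channels and 100 s segments for pipeline properties, the full
14-subject reference geometry for bookkeeping and stage-gradient checks
(at 12 channels for the gradient battery, since gradient directions do not
depend on channel count), 200 replicate null cohorts for type-I
calibration, and 3-split classification with the reduced grid. These sizes
are package choices and can be raised freely; the full 30-channel,
150-combination configuration is exposed through `pipeline_config()`.

## Known limitations

* EDF input/output is not implemented; recordings enter either from the
  generator or through the plain-text CSV + JSON exchange format
  (`write_recording()` / `read_recording()`).
* The Shapiro–Wilk screen subsamples above 5000 values (the test's domain
  limit) rather than switching tests.
* iCOH equivariance under channel permutation holds up to sign, a direct
  consequence of storing the signed `i < j` value in a symmetric matrix.
* The N2 burst model shares the beta-band mixing geometry; it creates
  spindle-band coupling and power but no realistic spindle morphology
  (no frequency chirp, no amplitude asymmetry).
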