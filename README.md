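# phasesleep

EEG functional connectivity changes systematically with sleep depth: phase
coupling between distant scalp electrodes strengthens in the delta band and
weakens in the alpha band as NREM sleep deepens, and these coupling patterns
alone carry enough information to classify AASM sleep stages (W, N1, N2, N3)
by machine learning. `phasesleep` implements that analysis as a reusable R
pipeline for researchers working on sleep, consciousness, and EEG network
inference: six Hilbert-based phase-coupling metrics per frequency band and
10 s epoch, nonparametric stage-difference statistics, and subject-wise
gradient-boosted sleep-stage classification — together with a synthetic EEG
cohort generator so that every stage of the pipeline is testable without
access to clinical recordings.

## The metrics

Each channel's band-passed signal `x(t)` is extended to its analytic signal
`x(t) + i x_H(t) = A(t) e^{iφ(t)}` (Hilbert transform `x_H`), giving
instantaneous amplitude `A(t)` and phase `φ(t)`. For channels *i*, *j* the
per-sample cross-spectrum is

    S_ij(t) = A_i(t) A_j(t) exp(+i Δφ_ij(t)),   Δφ_ij = φ_i − φ_j,

with power series `S_ii = A_i²`. With `⟨·⟩` the time average over one 10 s
epoch, the six coupling metrics are

| metric | definition | amplitude-sensitive | zero-lag-sensitive |
|---|---|---|---|
| COH   | `\|⟨S_ij⟩\| / √(⟨S_ii⟩⟨S_jj⟩)` | yes | yes |
| iCOH  | `Im(⟨S_ij⟩ / √(⟨S_ii⟩⟨S_jj⟩))` | yes | no |
| PLV   | `\|⟨e^{iΔφ}⟩\|` | no | yes |
| ciPLV | `\|⟨Im e^{iΔφ}⟩\| / √(1 − ⟨Re e^{iΔφ}⟩²)` | no | no |
| PLI   | `\|⟨sign(Im S_ij)⟩\|` | no | no |
| wPLI  | `\|⟨Im S_ij⟩\| / ⟨\|Im S_ij\|⟩` | no | no |

Zero-lag-insensitive metrics discard instantaneous correlations, the
signature of volume conduction (one source appearing simultaneously at many
electrodes). The four analysis bands are delta 1–3.5 Hz, theta 4.5–7 Hz,
alpha 8–12 Hz and beta 13–30 Hz, separated by ≥ 1 Hz guard gaps; filtering
uses a 6th-order zero-phase Butterworth band-pass. For a 30-channel montage
each metric yields 435 channel pairs × 4 bands = 1740 features per epoch.

Downstream, subject-by-stage tables of band-averaged coupling are tested
with Friedman omnibus tests (Bonferroni-controlled over the 6 × 4 = 24
metric/band families, α = 0.05/24 ≈ 0.00208) and Nemenyi post-hoc pairwise
stage comparisons; stages are classified per metric with gradient-boosted
trees under strictly subject-wise 80/20 splits (11 train / 3 test of 14
subjects, 30 splits) with subject-grouped 5-fold cross-validated grid
search.

## Worked example

```r
library(phasesleep)

spec   <- cohort_spec(n_subjects = 4, segment_length_s = 100,
                      n_channels = 10, seed = 1)
cohort <- generate_cohort(default_stage_profiles(), spec)
fc     <- cohort_features(cohort, metrics = "PLV", include_power = FALSE)
fc
#> <fc_features> 160 epochs, 4 subjects, metrics: PLV (180 features each)

tabs <- subject_stage_tables(fc, "PLV")
round(colMeans(tabs$alpha), 3)
#>     W    N1    N2    N3
#> 0.309 0.213 0.164 0.152
round(colMeans(tabs$delta), 3)
#>     W    N1    N2    N3
#> 0.181 0.189 0.204 0.247

fr <- friedman_rank_test(tabs$alpha)
sprintf("Friedman chi2 = %.2f, p = %.4g", fr$statistic, fr$p)
#> "Friedman chi2 = 12.00, p = 0.007383"
round(nemenyi_test(tabs$alpha), 3)
#>        W    N1    N2    N3
#> W  1.000 0.692 0.126 0.006
#> N1 0.692 1.000 0.692 0.126
#> N2 0.126 0.692 1.000 0.692
#> N3 0.006 0.126 0.692 1.000
```

The alpha-band phase-locking value falls monotonically from wakefulness
(0.309) into deep sleep (0.152) while delta-band coupling rises
(0.181 → 0.247) — the stage gradient the statistics and the classifier
exploit. The Friedman test rejects equality of stages for alpha PLV, and
the Nemenyi matrix localises the difference to the W–N3 contrast
(p = 0.006). `run_pipeline(pipeline_config(...), out_dir)` runs the whole
chain (synthesis → features → statistics → classification) and writes CSV/
JSON outputs plus a hash manifest.

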