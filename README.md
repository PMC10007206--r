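# jitterhrv

Heartbeat timing jitter versus HRV-based sleep staging: a seeded simulation
pipeline.

Ballistocardiography (BCG) can sense heartbeats without any sensor on the
body, which makes it attractive for long-term sleep monitoring — but its J
peaks are noisier timing fiducials than ECG R peaks, so heart-rate-
variability (HRV) features computed from BCG heartbeat intervals (HBIs)
differ from their ECG counterparts. This package quantifies what that
timing error costs a downstream HRV-based sleep stager, and bounds where
real BCG systems sit on the resulting cost curve. It is written for
researchers in unobtrusive cardiac monitoring and sleep physiology who
want the full simulation — data generation to error curves — reproducible
from one seed.

## What it computes

- **Synthetic study material** (`cohort_spec()`, `generate_cohort()`,
  `generate_beat_pairs()`): a cohort of nights, each a hypnogram (30-s
  epochs; Wake/S1/S2/S3/REM with occupancy 30.0/2.6/41.1/11.6/14.7% and
  8.43 ± 0.5 h nights) plus an R-peak stream with stage-dependent RR
  dynamics (LF/HF sinusoids, very-low-frequency wander, bout-to-bout
  variability); and a 27 × 100 table of paired ECG-R/BCG-J beat timings.
- **Label cleaning** (`merge_s4()`, `merge_short_runs()`, `to_macro()`):
  S4 → S3, absorption of stage runs shorter than 4 epochs into their
  predecessor, and the five-class → three-class (Wake/NREM/REM) collapse.
- **Jitter ladder** (`perturb_rpeaks()`, `build_ladder()`): 97 Gaussian
  timing-jitter severities calibrated so the top level's pooled mean
  absolute HBI error is 60 ms, via the closed form `MAE = 2σ/√π`.
- **HRV features** (`compute_features()`): per epoch, from five-minute
  windows with 90% overlap — HR (mean interval), SDNN, and LF
  (0.04–0.15 Hz) / HF (0.15–0.4 Hz) band powers of the normalized
  Lomb–Scargle periodogram of the unevenly sampled interval series
  (Rcpp implementation), plus LFHF and its running median.
- **Staging sensitivity** (`cv_error()`, `evaluate_cohort()`,
  `sensitivity_slope()`, `ensemble_curve()`): per-participant stratified
  10-fold CV with a Gaussian-kernel one-vs-one SVM and kNN, kNN-based
  Bayes-error brackets `((L-1)/L)(1-√(1-(L/(L-1))e)) ≤ E_bayes ≤ e`, error
  curves over the ladder, and per-feature error-vs-MAE slopes (%/s).
- **Timing-error bound** (`total_bound()`, `project_error()`): the
  triangle-inequality bound `|e_T| ≤ |RGI| + |e_p|` on total BCG timing
  error from beat-pair tables (RGI deviations centred per participant),
  and its projection onto the error curves.

## Worked example

```r
library(jitterhrv)

# three synthetic nights
co <- generate_cohort(cohort_spec(n_participants = 3, seed = 1))
co$hypnograms[[1]]
#> <hypnogram> 976 epochs of 30 s (micro)
#>     R    S1    S2    S3     W 
#> 0.113 0.020 0.350 0.149 0.368

# a small jitter ladder calibrated to 60 ms terminal MAE
lad <- build_ladder(co$streams, n_levels = 10, target_mae_ms = 60, seed = 1)
round(lad$pooled_mae_ms, 1)
#>  [1]  6.0 12.0 17.9 23.9 30.0 35.7 41.8 47.8 54.0 60.0

# features at baseline and top severity, and their staging cost
stacks <- lapply(1:3, function(i)
  feature_stack(co$streams[[i]], co$hypnograms[[i]], lad, i, c(0, 10)))
names(stacks) <- names(co$streams)
res <- evaluate_cohort(stacks, co$hypnograms, lad, c(0, 10), "macro")
ensemble_curve(res)[, c("level", "mae_ms", "mean")]
#> # A tibble: 2 × 3
#>   level mae_ms  mean
#>   <dbl>  <dbl> <dbl>
#> 1     0    0    20.2
#> 2    10   60.0  25.6
```

The pooled MAE climbs linearly to the 60 ms target (the closed-form sigma
schedule), and the ensemble macro-labeling error rises from 20% at zero
jitter to 26% at 60 ms on this three-night toy cohort — the degradation the
full study measures on 10 nights across 21 severities.

The full analysis is the numbered scripts in `analysis/` (simulate →
ladder → features → staging → bound), each writing its tables under
`results/`; `run_pipeline()` runs the same stages from a single YAML/JSON
config with per-stage caching.

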