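# Shared fixtures. The study-scale cohort (10 participants, full nights) and
# everything derived from it are expensive, so they are built lazily once and
# cached for all test files.

.fx <- new.env(parent = emptyenv())

with_seed <- jitterhrv:::with_seed

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# 10-night cohort under the default specification.
fx_cohort <- function() fx_get("cohort", function() {
  generate_cohort(cohort_spec(n_participants = 10L, seed = 1L))
})

# Full 97-level severity ladder (calibration object).
fx_ladder97 <- function() fx_get("ladder97", function() {
  build_ladder(fx_cohort()$streams, n_levels = 97L, target_mae_ms = 60,
               seed = 1L)
})

# 20-level ladder used for the classification sweep.
fx_ladder20 <- function() fx_get("ladder20", function() {
  build_ladder(fx_cohort()$streams, n_levels = 20L, target_mae_ms = 60,
               seed = 1L)
})

# Per-participant feature stacks across levels 0..20 of the 20-level ladder.
fx_stacks <- function() fx_get("stacks", function() {
  co <- fx_cohort()
  lad <- fx_ladder20()
  st <- lapply(seq_along(co$streams), function(i)
    feature_stack(co$streams[[i]], co$hypnograms[[i]], lad, i, 0:20))
  names(st) <- names(co$streams)
  st
})

# All-feature evaluation (SVM + kNN) per scheme over levels 0..20.
fx_eval <- function(scheme) fx_get(paste0("eval_", scheme), function() {
  co <- fx_cohort()
  evaluate_cohort(fx_stacks(), co$hypnograms, fx_ladder20(), 0:20, scheme,
                  "all", seed = 1L)
})

# Single-feature sensitivity sweep on a thinned level grid; returns the
# across-participant mean OLS slope (%/s) per feature.
fx_slopes <- function(scheme) fx_get(paste0("slopes_", scheme), function() {
  co <- fx_cohort()
  lv <- seq(0L, 20L, by = 4L)
  vapply(jitterhrv:::HRV_FEATURES, function(f) {
    r <- evaluate_cohort(fx_stacks(), co$hypnograms, fx_ladder20(), lv,
                         scheme, f, seed = 1L)
    mean(vapply(split(r, r$participant_id), function(p)
      as.numeric(sensitivity_slope(p$mae_ms / 1000, p$error_pct)),
      numeric(1)))
  }, numeric(1))
})

# A short single night (compact fixture for feature-bookkeeping tests).
fx_short_night <- function(n_epochs = 120L, seed = 7L) {
  fx_get(paste0("short_", n_epochs, "_", seed), function() {
    spec <- cohort_spec(n_participants = 1L,
                        duration_mean_h = n_epochs * 30 / 3600,
                        duration_sd_h = 0, min_duration_h = 0.5, seed = seed)
    hyp <- merge_s4(generate_hypnogram(spec, seed))
    stream <- generate_rpeaks(hyp, stage_hrv_params(), seed, "short")
    list(hyp = hyp, stream = stream)
  })
}

# Independent brute-force re-implementation of the short-run merging rule:
# explicit epoch-index scanning, first short run merged per pass, repeated
# to a fixed point. Oracle for merge_short_runs.
brute_merge_short_runs <- function(labs, min_epochs) {
  repeat {
    runs <- list()
    i <- 1L
    n <- length(labs)
    while (i <= n) {
      j <- i
      while (j < n && labs[j + 1L] == labs[i]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    }
    if (length(runs) == 1L) break
    changed <- FALSE
    for (k in seq_along(runs)) {
      len <- runs[[k]][2] - runs[[k]][1] + 1L
      if (len < min_epochs) {
        src <- if (k == 1L) runs[[2L]][1] else runs[[k - 1L]][1]
        labs[runs[[k]][1]:runs[[k]][2]] <- labs[src]
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  labs
}
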