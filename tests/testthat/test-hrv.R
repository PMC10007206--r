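# Windowing, Lomb-Scargle spectra, and the per-epoch feature matrix.

test_that("epoch windows are centred, stepped on the epoch grid, and clipped", {
  spec <- window_spec()
  expect_equal(spec$step_s, 30) # 300 s width at 90% overlap
  w <- window_for_epoch(10, spec, c(0, 3600))
  expect_equal(unname(w[c("lo", "hi")]), c(165, 465))
  expect_equal(unname(w["clipped"]), 0)
  w0 <- window_for_epoch(0, spec, c(0, 3600))
  expect_equal(unname(w0[c("lo", "hi")]), c(0, 165))
  expect_equal(unname(w0["clipped"]), 1)
  expect_error(window_for_epoch(200, spec, c(0, 3600)), "outside")
})

test_that("the periodogram agrees with a direct-sum evaluation of the definition", {
  set.seed(4)
  t <- cumsum(runif(300, 0.7, 1.3))
  y <- 0.04 * sin(2 * pi * 0.11 * t) + rnorm(300, 0, 0.02)
  spec <- window_spec()
  pg <- ls_periodogram(hbi_series(t, y + 1), spec)
  direct <- function(f) {
    yc <- y - mean(y)
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2)) /
      (2 * stats::var(yc))
  }
  idx <- c(3, 43, 99, 180)
  expect_equal(pg$power[idx], vapply(pg$freq_hz[idx], direct, numeric(1)),
               tolerance = 1e-10)
})

test_that("band power localizes sinusoidal modulation in the right band", {
  set.seed(5)
  t <- cumsum(runif(400, 0.8, 1.2))
  hf_mod <- hbi_series(t, 1 + 0.05 * sin(2 * pi * 0.25 * t) +
                         rnorm(400, 0, 0.005))
  lf <- lomb_band_power(hf_mod, c(0.04, 0.15))
  hf <- lomb_band_power(hf_mod, c(0.15, 0.4))
  expect_gt(hf / lf, 10)

  # constant series has zero variance, hence zero band power everywhere
  flat <- hbi_series(t, rep(1, 400))
  expect_equal(lomb_band_power(flat, c(0.04, 0.15)), 0)
  expect_equal(lomb_band_power(flat, c(0.15, 0.4)), 0)

  expect_error(lomb_band_power(hbi_series(t[1:10], rep(1, 10)),
                               c(0.04, 0.15)), "too few")
})

test_that("disjoint band powers recombine into the union band power", {
  set.seed(6)
  t <- cumsum(runif(350, 0.7, 1.3))
  h <- hbi_series(t, 1 + rnorm(350, 0, 0.03))
  spec <- window_spec()
  grid_n <- function(b) sum(spec$f_lo + (seq_len(spec$nf) - 1) * spec$f_step
                            >= b[1] - 1e-9 &
                            spec$f_lo + (seq_len(spec$nf) - 1) * spec$f_step
                            < b[2] - 1e-9)
  b1 <- c(0.04, 0.10); b2 <- c(0.10, 0.15); bu <- c(0.04, 0.15)
  n1 <- grid_n(b1); n2 <- grid_n(b2)
  p1 <- lomb_band_power(h, b1, min_beats = 10)
  p2 <- lomb_band_power(h, b2, min_beats = 10)
  pu <- lomb_band_power(h, bu, min_beats = 10)
  expect_equal((n1 * p1 + n2 * p2) / (n1 + n2), pu, tolerance = 1e-12)
})

test_that("feature matrices keep the epoch bookkeeping straight", {
  sn <- fx_short_night()
  hb <- hbis_from_peaks(sn$stream)
  f <- compute_features(hb, sn$hyp)
  expect_equal(nrow(f), length(sn$hyp$labels))
  expect_equal(f$epoch_index, seq_len(nrow(f)) - 1L)
  expect_true(all(f$LF >= 0 & f$HF >= 0, na.rm = TRUE))
  expect_true(all(f$SDNN >= 0, na.rm = TRUE))
  ok <- !is.na(f$LFHF) & f$HF > 0
  expect_equal(f$LFHF[ok], (f$LF / f$HF)[ok])
  # boundary windows are clipped but interior ones are not
  expect_true(f$clipped[1] && f$clipped[nrow(f)])
  expect_false(any(f$clipped[6:(nrow(f) - 5)]))
})

test_that("constant intervals give HR equal to the interval and zero SDNN", {
  hyp <- hypnogram(rep("S2", 20))
  s <- rpeak_stream(0:599, "c")
  f <- compute_features(hbis_from_peaks(s), hyp)
  expect_true(all(abs(f$HR - 1) < 1e-12))
  expect_true(all(f$SDNN < 1e-12))
  # constant LFHF column passes through the median filter unchanged
  x <- rep(2.5, 40)
  expect_equal(jitterhrv:::running_median(x, 5), x)
})

test_that("level 0 of a feature stack equals the baseline feature matrix", {
  sn <- fx_short_night()
  lad <- build_ladder(list(s = sn$stream), n_levels = 3, target_mae_ms = 40,
                      seed = 1)
  st <- feature_stack(sn$stream, sn$hyp, lad, 1, levels = c(0, 2))
  base <- compute_features(hbis_from_peaks(sn$stream, 0), sn$hyp)
  expect_equal(st[st$level == 0, ], base)
  expect_equal(nrow(st), 2 * length(sn$hyp$labels))
})

test_that("windowed mean interval is far less jitter-sensitive than HF power", {
  sn <- fx_short_night()
  lad <- build_ladder(list(s = sn$stream), n_levels = 2, target_mae_ms = 60,
                      seed = 2)
  st <- feature_stack(sn$stream, sn$hyp, lad, 1, levels = c(0, 2))
  f0 <- st[st$level == 0, ]
  f2 <- st[st$level == 2, ]
  ok <- f0$valid & f2$valid
  rel_hr <- mean(abs(f2$HR - f0$HR)[ok]) / sd(f0$HR[ok])
  rel_hf <- mean(abs(f2$HF - f0$HF)[ok]) / sd(f0$HF[ok])
  expect_gt(rel_hf, 5 * rel_hr)
})
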