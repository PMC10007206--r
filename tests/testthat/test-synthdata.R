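# Synthetic cohort generator: hypnograms, R-peak streams, beat-pair tables.

test_that("epoch count follows night duration exactly when the draw is fixed", {
  spec <- cohort_spec(n_participants = 1, duration_mean_h = 8,
                      duration_sd_h = 0, seed = 1)
  hyp <- generate_hypnogram(spec, 1)
  expect_length(hyp$labels, 960) # 8 * 3600 / 30
})

test_that("degenerate occupancy produces a single-stage hypnogram", {
  spec <- cohort_spec(n_participants = 1, duration_mean_h = 7,
                      duration_sd_h = 0,
                      stage_props = c(W = 0, S1 = 0, S2 = 1, S3 = 0, R = 0),
                      seed = 3)
  hyp <- generate_hypnogram(spec, 3)
  expect_true(all(hyp$labels == "S2"))
})

test_that("generation is deterministic and participant-stable under one seed", {
  spec3 <- cohort_spec(n_participants = 3, seed = 11)
  spec5 <- cohort_spec(n_participants = 5, seed = 11)
  a <- generate_cohort(spec3, params = NULL)
  b <- generate_cohort(spec3, params = NULL)
  c5 <- generate_cohort(spec5, params = NULL)
  expect_identical(a$hypnograms, b$hypnograms)
  # enlarging the cohort must not perturb existing participants
  expect_identical(lapply(a$hypnograms, `[[`, "labels"),
                   lapply(c5$hypnograms[1:3], `[[`, "labels"))
  p1 <- generate_beat_pairs(n_participants = 5, seed = 4)
  p2 <- generate_beat_pairs(n_participants = 5, seed = 4)
  expect_identical(p1, p2)
})

test_that("invalid cohort specifications are rejected with informative errors", {
  expect_error(cohort_spec(stage_props = c(W = 0.5, S1 = 0.1, S2 = 0.2,
                                           S3 = 0.1, R = 0.2)), "sum to 1")
  expect_error(cohort_spec(mean_dwell_epochs = c(W = 0.5, S1 = 6, S2 = 16,
                                                 S3 = 9, R = 12)), ">= 1")
  expect_error(cohort_spec(duration_mean_h = -1), "positive")
  expect_error(hypnogram(character(0)), "non-empty")
  expect_error(hypnogram(c("W", "X")), "alphabet")
})

test_that("noise-free unit-interval parameters give beats on the integer grid", {
  tab <- data.frame(stage = c("W", "S1", "S2", "S3", "R"), mean_rr = 1,
                    lf_amp = 0, hf_amp = 0, lf_freq = 0.1, hf_freq = 0.25,
                    noise_sd = 0)
  params <- stage_hrv_params(tab, vlf_amp = 0)
  hyp <- hypnogram(rep("S2", 20))
  s <- generate_rpeaks(hyp, params, seed = 1)
  expect_equal(s$times, 0:599)
})

test_that("generated streams are strictly increasing with plausible intervals", {
  co <- generate_cohort(cohort_spec(n_participants = 2, seed = 5))
  for (s in co$streams) {
    d <- diff(s$times)
    expect_true(all(d > 0.2 & d < 4))
    # stream spans the full hypnogram
  }
  expect_gte(max(co$streams[[1]]$times),
             (length(co$hypnograms[[1]]$labels) - 1) * 30)
})

test_that("a pure HF modulation shows up at its frequency in the periodogram", {
  tab <- data.frame(stage = c("W", "S1", "S2", "S3", "R"), mean_rr = 1,
                    lf_amp = 0, hf_amp = 0.05, lf_freq = 0.1, hf_freq = 0.25,
                    noise_sd = 0.005)
  params <- stage_hrv_params(tab, vlf_amp = 0)
  hyp <- hypnogram(rep("S2", 40))
  s <- generate_rpeaks(hyp, params, seed = 2)
  pg <- ls_periodogram(hbis_from_peaks(s))
  f_peak <- pg$freq_hz[which.max(pg$power)]
  expect_lte(abs(f_peak - 0.25), 0.0025) # within one grid step
})

test_that("well-separated stage baselines separate window means with no overlap", {
  tab <- data.frame(stage = c("W", "S1", "S2", "S3", "R"),
                    mean_rr = c(0.8, 0.9, 0.95, 1.1, 0.85),
                    lf_amp = 0.01, hf_amp = 0.01, lf_freq = 0.1,
                    hf_freq = 0.25, noise_sd = 0.01)
  params <- stage_hrv_params(tab, vlf_amp = 0)
  hyp_w <- hypnogram(rep("W", 30))
  hyp_s3 <- hypnogram(rep("S3", 30))
  f_w <- compute_features(hbis_from_peaks(generate_rpeaks(hyp_w, params, 1)),
                          hyp_w)
  f_s3 <- compute_features(hbis_from_peaks(generate_rpeaks(hyp_s3, params, 1)),
                           hyp_s3)
  expect_gt(min(f_s3$HR), max(f_w$HR))
})

test_that("beat-pair tables have the demanded shape and error statistics", {
  tab <- generate_beat_pairs(seed = 1)
  expect_equal(nrow(tab), 2700) # 27 participants x 100 beats
  expect_true(all(tab$rgi_ms > 0))
  expect_equal(unname(table(tab$participant_id)), rep(100L, 27),
               ignore_attr = TRUE)

  # rgi_sd = 0 makes the centred RGI jitter identically zero
  t0 <- generate_beat_pairs(n_participants = 3, rgi_sd_ms = 0, seed = 2)
  expect_equal(rgi_jitter(t0), rep(0, nrow(t0)))

  # half-normal law: mean |ep| -> sigma * sqrt(2/pi) at large n
  tb <- generate_beat_pairs(n_participants = 100, ep_sd_ms = 10, seed = 3)
  expect_equal(mean(abs(tb$ep_ms)), 10 * sqrt(2 / pi), tolerance = 0.03)
})

test_that("overly aggressive RR parameters fail loudly", {
  tab <- data.frame(stage = c("W", "S1", "S2", "S3", "R"), mean_rr = 0.5,
                    lf_amp = 0.1, hf_amp = 0.1, lf_freq = 0.1,
                    hf_freq = 0.25, noise_sd = 0.06)
  expect_error(stage_hrv_params(tab), "aggressive|too large")
})

test_that("cohort CSV round-trips preserve streams and hypnograms", {
  co <- generate_cohort(cohort_spec(n_participants = 2, duration_mean_h = 6.2,
                                    seed = 8))
  d <- withr::local_tempdir()
  write_rpeaks_csv(co$streams, file.path(d, "rpeaks.csv"))
  write_hypnograms_csv(co$hypnograms, file.path(d, "hyp.csv"))
  s2 <- read_rpeaks_csv(file.path(d, "rpeaks.csv"))
  h2 <- read_hypnograms_csv(file.path(d, "hyp.csv"))
  expect_equal(s2[["p01"]]$times, co$streams[["p01"]]$times)
  expect_equal(h2[["p02"]]$labels, co$hypnograms[["p02"]]$labels)
})
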