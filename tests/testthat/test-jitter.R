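# Jitter injection, HBI derivation, MAE, and the severity ladder.

make_stream <- function(n, rr = 1.0, id = "s") {
  rpeak_stream(seq(0, by = rr, length.out = n), id)
}

test_that("zero jitter is the identity and beat count is conserved", {
  s <- make_stream(500)
  expect_identical(perturb_rpeaks(s, 0, 1), s)
  p <- perturb_rpeaks(s, 30, 1)
  expect_length(p$times, 500)
  expect_true(all(diff(p$times) > 0))
})

test_that("HBI series are insensitive to a constant time offset", {
  s <- make_stream(200)
  shifted <- rpeak_stream(s$times + 0.35, "s")
  expect_equal(hbis_from_peaks(shifted)$intervals,
               hbis_from_peaks(s)$intervals)
})

test_that("realized perturbations match the requested Gaussian scale", {
  s <- make_stream(10000)
  p <- perturb_rpeaks(s, 20, 3)
  expect_equal(sd(p$times - s$times) * 1000, 20, tolerance = 0.03)
})

test_that("interval derivation and MAE follow their definitions", {
  h <- hbis_from_peaks(rpeak_stream(c(0, 1, 2), "x"))
  expect_equal(h$intervals, c(1, 1))
  expect_equal(h$timestamps, c(1, 2))
  h2 <- hbis_from_peaks(rpeak_stream(c(0, 0.8, 1.9), "x"))
  expect_equal(h2$intervals, c(0.8, 1.1))
  expect_error(hbis_from_peaks(rpeak_stream(0.5, "x")), "2 beats")

  a <- hbi_series(c(1, 2), c(1.00, 1.00))
  b <- hbi_series(c(1.01, 1.99), c(1.01, 0.98))
  expect_equal(hbi_mae(a, a), 0)
  expect_equal(hbi_mae(a, b), 15) # (0.01 + 0.02)/2 s = 15 ms
  expect_error(hbi_mae(a, hbi_series(1, 1)), "length")
})

test_that("realized MAE follows the closed-form 2 sigma / sqrt(pi) law", {
  s <- make_stream(30001)
  base <- hbis_from_peaks(s)
  for (sigma in c(10, 40)) {
    mae <- hbi_mae(hbis_from_peaks(perturb_rpeaks(s, sigma, 5)), base)
    expect_equal(mae, 2 * sigma / sqrt(pi), tolerance = 0.02)
  }
})

test_that("the ladder calibrates to its target, rises monotonically, and reproduces", {
  streams <- list(a = make_stream(4000, 0.9, "a"),
                  b = make_stream(4000, 1.1, "b"))
  lad <- build_ladder(streams, n_levels = 8, target_mae_ms = 60, seed = 2)
  expect_length(lad$sigmas_ms, 8)
  expect_true(all(diff(lad$sigmas_ms) > 0))
  expect_equal(tail(lad$pooled_mae_ms, 1), 60, tolerance = 2 / 60)
  expect_true(all(diff(lad$pooled_mae_ms) > -0.5))
  lad2 <- build_ladder(streams, n_levels = 8, target_mae_ms = 60, seed = 2)
  expect_identical(lad$mae_ms, lad2$mae_ms)
  expect_error(build_ladder(list(make_stream(50))), ">= 100 beats")
})

test_that("ladder streams are regenerable from their seeds", {
  streams <- list(a = make_stream(1000, 1.0, "a"))
  lad <- build_ladder(streams, n_levels = 3, target_mae_ms = 40, seed = 9)
  s1 <- ladder_stream(streams[[1]], lad, 1, 2)
  s2 <- ladder_stream(streams[[1]], lad, 1, 2)
  expect_identical(s1$times, s2$times)
  expect_identical(ladder_stream(streams[[1]], lad, 1, 0), streams[[1]])
  d <- withr::local_tempdir()
  write_ladder_json(lad, file.path(d, "lad.json"))
  lad2 <- read_ladder_json(file.path(d, "lad.json"))
  expect_equal(lad2$sigmas_ms, lad$sigmas_ms)
  expect_equal(lad2$mae_ms, lad$mae_ms)
})
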