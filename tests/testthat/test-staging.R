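# Cross-validated staging, Bayes bounds, slopes, ensembles, confusions.

fake_features <- function(x, valid = TRUE) {
  n <- nrow(x)
  out <- tibble::tibble(epoch_index = seq_len(n) - 1L, level = 0L,
                        n_beats = 100L, clipped = FALSE,
                        HR = x[, 1], SDNN = x[, 2], LF = x[, 3], HF = x[, 4],
                        LFHF = x[, 5], MedFiltLFHF = x[, 6],
                        valid = rep(valid, n))
  out
}

blob_data <- function(n_per, sep, seed = 1) {
  with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 6), ncol = 6),
               matrix(rnorm(n_per * 6, mean = sep), ncol = 6))
    list(x = x, y = rep(c("W", "S2"), each = n_per))
  })
}

test_that("well-separated classes are classified almost perfectly", {
  d <- blob_data(100, 6)
  err <- cv_error(fake_features(d$x), d$y, eval_config("svm", seed = 1))
  expect_lt(as.numeric(err), 2)
})

test_that("permuted labels sit at chance level", {
  with_seed(2, {
    x <- matrix(rnorm(600 * 6), ncol = 6)
    y <- sample(c("W", "S2", "R"), 600, TRUE, prob = c(0.5, 0.3, 0.2))
  })
  err <- cv_error(fake_features(x), y, eval_config("svm", seed = 3))
  chance <- 100 * (1 - max(table(y)) / length(y))
  expect_equal(as.numeric(err), chance, tolerance = 3 / chance)
})

test_that("cross-validation is deterministic given a seed and flags sparse classes", {
  d <- blob_data(60, 2, seed = 5)
  cfg <- eval_config("svm", seed = 7)
  e1 <- cv_error(fake_features(d$x), d$y, cfg)
  e2 <- cv_error(fake_features(d$x), d$y, cfg)
  expect_identical(as.numeric(e1), as.numeric(e2))
  expect_false(attr(e1, "flagged"))
  # a class rarer than the fold count is computed but flagged
  y <- c(rep("W", 115), rep("S1", 5))
  x <- rbind(matrix(rnorm(115 * 6), ncol = 6),
             matrix(rnorm(5 * 6, 4), ncol = 6))
  ef <- cv_error(fake_features(x), y, eval_config("svm", seed = 1))
  expect_true(attr(ef, "flagged"))
  expect_error(cv_error(fake_features(x), rep("W", 120),
                        eval_config("svm")), "2 classes")
})

test_that("kNN backend classifies and feeds the Bayes machinery", {
  d <- blob_data(100, 5, seed = 8)
  err <- cv_error(fake_features(d$x), d$y, eval_config("knn", seed = 2))
  expect_lt(as.numeric(err), 5)
})

test_that("Bayes bounds follow the closed formula and its sanity properties", {
  b0 <- bayes_bounds(0, 5)
  expect_equal(c(b0$lower, b0$upper), c(0, 0))
  b2 <- bayes_bounds(0.5, 2)
  expect_equal(c(b2$lower, b2$upper), c(0.5, 0.5)) # saturates at chance
  b5 <- bayes_bounds(0.2, 5)
  expect_equal(b5$lower, 0.8 * (1 - sqrt(1 - 1.25 * 0.2)), tolerance = 1e-12)
  expect_equal(b5$lower, 0.1072, tolerance = 1e-3)
  # monotone in e_knn, sandwiched below the upper bound
  e <- seq(0, 0.79, by = 0.01)
  b <- bayes_bounds(e, 5)
  expect_true(all(diff(b$lower) > 0))
  expect_true(all(b$lower <= b$upper + 1e-12))
  expect_error(bayes_bounds(0.9, 5), "exceeds")
})

test_that("sensitivity slopes recover exact and noisy linear trends", {
  mae <- seq(0, 0.06, length.out = 20)
  expect_equal(as.numeric(sensitivity_slope(mae, rep(25, 20))), 0)
  expect_equal(as.numeric(sensitivity_slope(mae, 10 + 50 * mae)), 50,
               tolerance = 1e-12)
  expect_error(sensitivity_slope(rep(0.01, 5), rnorm(5)), "degenerate")
  expect_error(sensitivity_slope(c(0, 0.1), c(1, 2)), "3 points")
})

test_that("ensemble curves summarize participants with exact moments", {
  cur <- tibble::tibble(
    participant_id = rep(c("a", "b"), each = 2),
    level = rep(c(0, 1), 2), mae_ms = rep(c(0, 10), 2),
    error_pct = c(10, 12, 30, 28))
  ec <- ensemble_curve(cur)
  expect_equal(ec$mean, c(20, 20))
  expect_equal(ec$sd[1], sd(c(10, 30)))
  expect_equal(ec$lo, ec$mean - 1.96 * ec$sd)
  # identical curves collapse the band onto the mean
  same <- cur; same$error_pct <- rep(c(5, 6), 2)
  expect_true(all(ensemble_curve(same)$sd == 0))
  # random curves against hand-computed moments
  with_seed(3, {
    m <- matrix(runif(5 * 4, 10, 40), 5, 4) # 5 participants x 4 levels
  })
  cur2 <- tibble::tibble(
    participant_id = rep(letters[1:5], each = 4),
    level = rep(1:4, 5), mae_ms = rep(1:4, 5) * 5,
    error_pct = as.vector(t(m)))
  ec2 <- ensemble_curve(cur2)
  expect_equal(ec2$mean, colMeans(m))
  expect_equal(ec2$sd, apply(m, 2, sd))
})

test_that("confusion pooling drops participants with empty detection columns", {
  cls <- c("W", "S2", "R")
  mk <- function(m) {
    dimnames(m) <- list(true = cls, predicted = cls)
    as.table(m)
  }
  good1 <- mk(matrix(c(5, 1, 0, 1, 6, 1, 0, 1, 5), 3, byrow = TRUE))
  good2 <- mk(matrix(c(4, 2, 1, 0, 7, 1, 1, 0, 4), 3, byrow = TRUE))
  bad <- mk(matrix(c(5, 2, 0, 1, 9, 0, 1, 2, 0), 3, byrow = TRUE)) # R never predicted
  pooled <- aggregate_confusion(list(good1, good2, bad))
  expect_equal(attr(pooled, "n_excluded"), 1)
  expect_equal(as.vector(pooled), as.vector(good1 + good2))
  expect_equal(as.vector(aggregate_confusion(list(good1, good2))),
               as.vector(good1 + good2))
  allbad <- list(bad, bad)
  expect_error(aggregate_confusion(allbad), "empty detection column")
})
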