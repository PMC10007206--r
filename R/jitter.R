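# Gaussian timing-jitter injection and the calibrated severity ladder.
#
# Each jitter level perturbs every beat time with an independent zero-mean
# Gaussian offset of SD sigma_n. The severity of a level is summarized by
# MAE_n, the mean absolute difference between the level-n heartbeat-interval
# (HBI) series and the unjittered baseline series. For interval errors the
# difference of two independent N(0, sigma^2) offsets is N(0, 2 sigma^2),
# whose mean absolute value is 2 sigma / sqrt(pi) -- the closed form used to
# place the ladder's sigma schedule.

#' Heartbeat-interval series
#'
#' @param timestamps time of each interval's trailing beat (s), strictly
#'   increasing.
#' @param intervals heartbeat intervals (s), all positive.
#' @param level jitter level the series derives from (0 = unjittered).
#' @return object of class `hbi_series`.
#' @export
hbi_series <- function(timestamps, intervals, level = 0L) {
  if (length(timestamps) != length(intervals))
    stop("timestamps and intervals must have equal length")
  if (any(intervals <= 0)) stop("intervals must be positive")
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  structure(list(timestamps = as.numeric(timestamps),
                 intervals = as.numeric(intervals),
                 level = as.integer(level)),
            class = "hbi_series")
}

#' Perturb an R-peak stream with Gaussian timing jitter
#'
#' Every beat time receives an independent `N(0, sigma^2)` offset; the
#' result is re-sorted so the stream stays strictly increasing (at the
#' severities used here inversions are possible but rare). Beat count is
#' preserved.
#'
#' @param stream an [rpeak_stream()].
#' @param sigma_ms jitter SD in milliseconds, >= 0.
#' @param seed integer seed.
#' @return a perturbed [rpeak_stream()] (plausibility validation off).
#' @export
perturb_rpeaks <- function(stream, sigma_ms, seed = 1L) {
  if (!inherits(stream, "rpeak_stream")) stop("stream must be an rpeak_stream")
  if (sigma_ms < 0) stop("sigma_ms must be >= 0")
  if (sigma_ms == 0) return(stream)
  t <- with_seed(seed,
    stream$times + stats::rnorm(length(stream$times), 0, sigma_ms / 1000))
  t <- sort(t)
  # ties have probability zero but would break downstream invariants
  while (any(diff(t) <= 0)) t <- sort(t + cumsum(c(0, diff(t) <= 0)) * 1e-9)
  rpeak_stream(t, stream$participant_id, validate = FALSE)
}

#' Derive the heartbeat-interval series of a stream
#'
#' Intervals are successive differences of the beat times; each interval is
#' stamped with its trailing beat's time.
#'
#' @param stream an [rpeak_stream()].
#' @param level jitter level recorded on the series.
#' @return an [hbi_series()].
#' @export
hbis_from_peaks <- function(stream, level = 0L) {
  if (length(stream$times) < 2) stop("need at least 2 beats")
  hbi_series(stream$times[-1], diff(stream$times), level)
}

#' Mean absolute error between two HBI series (ms)
#'
#' @param a,b [hbi_series()] of equal length (jitter preserves beat count,
#'   so a length mismatch signals upstream beat loss, which this model
#'   excludes).
#' @return MAE in milliseconds.
#' @export
hbi_mae <- function(a, b) {
  if (length(a$intervals) != length(b$intervals))
    stop("HBI series have different lengths; beat loss is outside this model")
  mean(abs(a$intervals - b$intervals)) * 1000
}

#' Build the jitter severity ladder
#'
#' `n_levels` linearly spaced jitter SDs ending at the value whose expected
#' HBI MAE equals `target_mae_ms` (closed form `sigma_max = target *
#' sqrt(pi) / 2`), then rescaled once by `target / realized` pooled MAE at
#' the top level so the terminal severity lands on the target despite
#' Monte-Carlo fluctuation. Each level's jitter is an independent
#' realization, seeded per participant x level, so levels are exchangeable
#' and reproducible.
#'
#' @param streams list of [rpeak_stream()] (the cohort); each needs >= 100
#'   beats.
#' @param n_levels number of severity levels.
#' @param target_mae_ms terminal pooled MAE target (ms).
#' @param seed base seed; per-level draws derive via [split_seed()].
#' @return object of class `jitter_ladder`: `sigmas_ms` (length
#'   `n_levels`), `mae_ms` (`n_levels` x participants matrix),
#'   `pooled_mae_ms`, `n_intervals`, plus the calibration inputs.
#' @export
build_ladder <- function(streams, n_levels = 97L, target_mae_ms = 60,
                         seed = 1L) {
  if (length(streams) == 0) stop("empty cohort")
  nb <- vapply(streams, function(s) length(s$times), integer(1))
  if (any(nb < 100)) stop("every stream needs >= 100 beats for calibration")
  n_p <- length(streams)
  base <- lapply(streams, hbis_from_peaks)
  n_int <- vapply(base, function(h) length(h$intervals), integer(1))

  pooled_mae_at <- function(sigma_ms, level) {
    tot <- 0
    for (i in seq_len(n_p)) {
      pert <- perturb_rpeaks(streams[[i]], sigma_ms,
                             split_seed(seed, i, level))
      tot <- tot + hbi_mae(hbis_from_peaks(pert), base[[i]]) * n_int[i]
    }
    tot / sum(n_int)
  }

  sigma_max <- target_mae_ms * sqrt(pi) / 2
  realized_top <- pooled_mae_at(sigma_max, n_levels)
  sigma_max <- sigma_max * target_mae_ms / realized_top
  sigmas <- seq_len(n_levels) * sigma_max / n_levels

  mae <- matrix(NA_real_, n_levels, n_p,
                dimnames = list(NULL, names(streams)))
  for (lev in seq_len(n_levels)) {
    for (i in seq_len(n_p)) {
      pert <- perturb_rpeaks(streams[[i]], sigmas[lev],
                             split_seed(seed, i, lev))
      mae[lev, i] <- hbi_mae(hbis_from_peaks(pert), base[[i]])
    }
  }
  pooled <- as.numeric(mae %*% n_int / sum(n_int))
  structure(list(sigmas_ms = sigmas, mae_ms = mae, pooled_mae_ms = pooled,
                 n_intervals = n_int, n_levels = as.integer(n_levels),
                 target_mae_ms = target_mae_ms, seed = as.integer(seed)),
            class = "jitter_ladder")
}

#' Reproduce the jittered stream of a ladder cell
#'
#' Levels are seeded per participant x level, so any jittered stream can be
#' regenerated from the ladder without storing it. Level 0 returns the
#' original stream.
#'
#' @param stream the participant's baseline [rpeak_stream()].
#' @param ladder a [build_ladder()] result.
#' @param participant_index 1-based index of the participant in the cohort
#'   the ladder was built from.
#' @param level jitter level, 0..`n_levels`.
#' @return [rpeak_stream()].
#' @export
ladder_stream <- function(stream, ladder, participant_index, level) {
  if (level == 0) return(stream)
  if (level < 0 || level > ladder$n_levels) stop("level out of range")
  perturb_rpeaks(stream, ladder$sigmas_ms[level],
                 split_seed(ladder$seed, participant_index, level))
}

#' Serialize / restore a jitter ladder as JSON
#'
#' @param ladder a `jitter_ladder`.
#' @param path JSON file path.
#' @return `path` (write) or a `jitter_ladder` (read).
#' @export
write_ladder_json <- function(ladder, path) {
  jsonlite::write_json(
    list(sigmas_ms = ladder$sigmas_ms,
         mae_ms = ladder$mae_ms,
         pooled_mae_ms = ladder$pooled_mae_ms,
         n_intervals = ladder$n_intervals,
         n_levels = ladder$n_levels,
         target_mae_ms = ladder$target_mae_ms,
         seed = ladder$seed,
         participants = colnames(ladder$mae_ms)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ladder_json
#' @export
read_ladder_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mae <- matrix(as.numeric(x$mae_ms), x$n_levels,
                dimnames = list(NULL, x$participants))
  ni <- as.integer(x$n_intervals)
  names(ni) <- x$participants
  structure(list(sigmas_ms = as.numeric(x$sigmas_ms), mae_ms = mae,
                 pooled_mae_ms = as.numeric(x$pooled_mae_ms),
                 n_intervals = ni,
                 n_levels = as.integer(x$n_levels),
                 target_mae_ms = x$target_mae_ms, seed = as.integer(x$seed)),
            class = "jitter_ladder")
}
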