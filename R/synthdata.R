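# Synthetic stand-ins for the two data archives the analysis was designed
# around: a polysomnography cohort (hypnogram + ECG R-peak stream per
# participant) and a laboratory table of paired ECG-R / BCG-J beat timings.

# Stage alphabets. Raw scoring may contain the non-standard S4 label; the
# cleaned micro scheme is five-class, the macro scheme three-class.
STAGES_RAW   <- c("W", "S1", "S2", "S3", "S4", "R")
STAGES_MICRO <- c("W", "S1", "S2", "S3", "R")
STAGES_MACRO <- c("Wake", "NREM", "REM")

#' Cohort specification for the synthetic sleep study
#'
#' Defines the marginal statistics of the generated cohort: night length
#' (truncated-normal, hours), the 30-s epoch grid, target stage occupancy
#' fractions, and mean stage dwell times for the semi-Markov hypnogram model.
#' The occupancy defaults are the study cohort's stage fractions (Wake 30.0%,
#' S1 2.6%, S2 41.1%, S3 11.6%, REM 14.7%) and nights average 8.43 +/- 0.5 h.
#'
#' @param n_participants number of nights/participants to generate.
#' @param epoch_s scoring epoch length in seconds.
#' @param duration_mean_h,duration_sd_h night-length distribution (hours);
#'   draws are truncated at `min_duration_h`.
#' @param min_duration_h lower truncation for night length (hours).
#' @param stage_props named target occupancy fractions over
#'   `c("W","S1","S2","S3","R")`; must sum to 1.
#' @param mean_dwell_epochs named mean run length (epochs) per stage for the
#'   geometric dwell-time model; all >= 1.
#' @param short_run_rate optional rate in `[0, 1)` at which extra one-epoch
#'   glitch runs and rare S4 labels are injected, to exercise the hypnogram
#'   cleaning rules; 0 (default) disables injection.
#' @param seed base seed; every participant's draws derive from it via
#'   [split_seed()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 50L,
                        epoch_s = 30,
                        duration_mean_h = 8.43,
                        duration_sd_h = 0.5,
                        min_duration_h = 6,
                        stage_props = c(W = 0.300, S1 = 0.026, S2 = 0.411,
                                        S3 = 0.116, R = 0.147),
                        mean_dwell_epochs = c(W = 7, S1 = 6, S2 = 10,
                                              S3 = 7, R = 8),
                        short_run_rate = 0,
                        seed = 1L) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (epoch_s <= 0) stop("epoch_s must be positive")
  if (duration_mean_h <= 0) stop("duration_mean_h must be positive")
  if (duration_sd_h < 0) stop("duration_sd_h must be non-negative")
  if (is.null(names(stage_props)) || !setequal(names(stage_props), STAGES_MICRO))
    stop("stage_props must be named over ", paste(STAGES_MICRO, collapse = ","))
  if (any(stage_props < 0)) stop("stage_props must be non-negative")
  if (abs(sum(stage_props) - 1) > 1e-9)
    stop("stage_props must sum to 1 (got ", sum(stage_props), ")")
  if (is.null(names(mean_dwell_epochs)) ||
      !all(names(stage_props) %in% names(mean_dwell_epochs)))
    stop("mean_dwell_epochs must cover every stage in stage_props")
  if (any(mean_dwell_epochs < 1)) stop("mean_dwell_epochs must be >= 1")
  if (short_run_rate < 0 || short_run_rate >= 1)
    stop("short_run_rate must be in [0, 1)")
  structure(list(
    n_participants = as.integer(n_participants),
    epoch_s = epoch_s,
    duration_mean_h = duration_mean_h,
    duration_sd_h = duration_sd_h,
    min_duration_h = min_duration_h,
    stage_props = stage_props[STAGES_MICRO],
    mean_dwell_epochs = mean_dwell_epochs[STAGES_MICRO],
    short_run_rate = short_run_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Hypnogram object
#'
#' @param labels character vector of stage codes, one per epoch.
#' @param epoch_s epoch length in seconds.
#' @param scheme `"micro"` (codes among W, S1, S2, S3, S4, R) or `"macro"`
#'   (Wake, NREM, REM).
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_s = 30, scheme = c("micro", "macro")) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  if (length(labels) == 0) stop("hypnogram must be non-empty")
  alphabet <- if (scheme == "micro") STAGES_RAW else STAGES_MACRO
  bad <- setdiff(unique(labels), alphabet)
  if (length(bad))
    stop("labels outside the ", scheme, " alphabet: ", paste(bad, collapse = ","))
  structure(list(labels = labels, epoch_s = epoch_s, scheme = scheme),
            class = "hypnogram")
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", length(x$labels), " epochs of ", x$epoch_s, " s (",
      x$scheme, ")\n", sep = "")
  print(round(prop.table(table(x$labels)), 3))
  invisible(x)
}

#' R-peak stream object
#'
#' Strictly increasing heartbeat fiducial times (seconds) for one participant.
#'
#' @param times numeric vector of beat times in seconds, strictly increasing.
#' @param participant_id identifier.
#' @param validate check the physiological-plausibility invariant on
#'   successive differences (0.2 s < RR < 4 s). Jitter perturbation disables
#'   it: large jitter may legitimately create very short intervals.
#' @return an object of class `rpeak_stream`.
#' @export
rpeak_stream <- function(times, participant_id = NA_character_,
                         validate = TRUE) {
  times <- as.numeric(times)
  if (length(times) < 2) stop("an R-peak stream needs at least 2 beats")
  d <- diff(times)
  if (any(d <= 0)) stop("beat times must be strictly increasing")
  if (validate && (any(d <= 0.2) || any(d >= 4)))
    stop("successive beat intervals outside (0.2, 4.0) s; implausible stream")
  structure(list(times = times, participant_id = participant_id),
            class = "rpeak_stream")
}

#' @export
print.rpeak_stream <- function(x, ...) {
  cat("<rpeak_stream> ", x$participant_id, ": ", length(x$times),
      " beats over ", round(max(x$times) / 3600, 2), " h\n", sep = "")
  invisible(x)
}

# Draw one night length (hours), truncated normal.
draw_night_hours <- function(spec) {
  repeat {
    h <- stats::rnorm(1, spec$duration_mean_h, spec$duration_sd_h)
    if (h >= spec$min_duration_h) return(h)
  }
}

#' Generate a synthetic hypnogram
#'
#' Semi-Markov stage process: successive stage visits are drawn i.i.d. with
#' entry probabilities proportional to `stage_props / mean_dwell_epochs`, and
#' each visit dwells a Geometric number of epochs with the stage's mean. The
#' long-run occupancy of this process is exactly `stage_props` (entry rate
#' times mean dwell), so pooled cohort fractions converge to the targets.
#' Repeated entries of the same stage are allowed and simply extend a run.
#'
#' With `short_run_rate > 0`, one-epoch glitch runs (drawn uniformly from the
#' raw alphabet including S4) are interleaved at that rate, providing material
#' for the label-cleaning rules.
#'
#' @param spec a [cohort_spec()].
#' @param participant_seed integer seed for this night (derive via
#'   [split_seed()] for cohort use).
#' @return a micro-coded [hypnogram()].
#' @export
generate_hypnogram <- function(spec, participant_seed = 1L) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  with_seed(participant_seed, {
    n_epochs <- round(draw_night_hours(spec) * 3600 / spec$epoch_s)
    props <- spec$stage_props
    dwell <- spec$mean_dwell_epochs
    active <- names(props)[props > 0]
    q <- props[active] / dwell[active]
    q <- q / sum(q)
    # discard a burn-in so the night starts in the stationary regime rather
    # than exactly at a run boundary (which overweights short-dwell stages)
    burn <- 120L
    labels <- character(0)
    while (length(labels) < n_epochs + burn) {
      s <- sample(active, 1L, prob = q)
      run <- stats::rgeom(1L, 1 / dwell[[s]]) + 1L
      labels <- c(labels, rep(s, run))
      if (spec$short_run_rate > 0 && stats::runif(1) < spec$short_run_rate)
        labels <- c(labels, sample(STAGES_RAW, 1L))
    }
    hypnogram(labels[burn + seq_len(n_epochs)], epoch_s = spec$epoch_s)
  })
}

#' Stage-dependent RR-dynamics parameters
#'
#' One row per micro stage: baseline interval `mean_rr` (s), LF and HF
#' sinusoidal modulation amplitudes (s) and frequencies (Hz, inside the
#' 0.04-0.15 Hz and 0.15-0.4 Hz HRV bands), and white-noise SD `noise_sd`
#' (s). A very-low-frequency wander term (`vlf_amp`, `vlf_freq`) shared
#' across stages models slow autonomic drift of the baseline heart rate
#' within the night; it lies below the LF band and is what keeps the
#' windowed-mean-interval feature from separating stages implausibly
#' cleanly.
#'
#' Defaults encode an autonomic gradient: deep sleep is slow and vagally
#' (HF) dominated, wake and REM are faster with more erratic beat-to-beat
#' noise; LF amplitude is nearly uniform so the LF feature's contrast comes
#' from the spectral normalization rather than raw LF power. Lognormal
#' bout-to-bout multipliers (`bout_cv`) add within-stage heterogeneity so no
#' feature reads a stage off a single noiseless parameter. The values are
#' package defaults chosen so that mean interval, SDNN and the spectral
#' features each carry some stage-discriminative signal; they are not
#' literature estimates.
#'
#' @param table data.frame with columns `stage, mean_rr, lf_amp, hf_amp,
#'   lf_freq, hf_freq, noise_sd` covering all five micro stages. Defaults
#'   supplied.
#' @param vlf_amp,vlf_freq shared baseline-wander amplitude (s) and
#'   frequency (Hz, below 0.04).
#' @param bout_cv log-scale SD of the lognormal bout-to-bout multiplier
#'   applied to `noise_sd` at every stage visit (no two wake bouts are
#'   alike); 0 disables it.
#' @param amp_cv log-scale SD of the corresponding multipliers on `lf_amp`
#'   and `hf_amp`; kept smaller than `bout_cv` so oscillatory content stays
#'   a more reliable stage marker than raw variability.
#' @return an object of class `stage_hrv_params`.
#' @export
stage_hrv_params <- function(table = NULL, vlf_amp = 0.06, vlf_freq = 0.0008,
                             bout_cv = 0.3, amp_cv = 0.15) {
  if (is.null(table)) {
    table <- data.frame(
      stage   = c("W",   "S1",  "S2",  "S3",  "R"),
      mean_rr = c(0.90,  0.94,  0.97,  1.01,  0.92),
      lf_amp  = c(0.016, 0.019, 0.022, 0.025, 0.015),
      hf_amp  = c(0.008, 0.020, 0.034, 0.050, 0.010),
      lf_freq = c(0.095, 0.095, 0.095, 0.095, 0.100),
      hf_freq = c(0.250, 0.250, 0.250, 0.250, 0.240),
      noise_sd = c(0.038, 0.029, 0.022, 0.015, 0.040)
    )
  }
  need <- c("stage", "mean_rr", "lf_amp", "hf_amp", "lf_freq", "hf_freq",
            "noise_sd")
  if (!all(need %in% names(table)))
    stop("params table must have columns ", paste(need, collapse = ","))
  if (!all(STAGES_MICRO %in% table$stage))
    stop("params table must cover stages ", paste(STAGES_MICRO, collapse = ","))
  with(table, {
    if (any(mean_rr < 0.4 | mean_rr > 2.0))
      stop("mean_rr must lie in [0.4, 2.0] s")
    if (any(lf_freq < 0.04 | lf_freq >= 0.15))
      stop("lf_freq must lie in [0.04, 0.15) Hz")
    if (any(hf_freq < 0.15 | hf_freq >= 0.4))
      stop("hf_freq must lie in [0.15, 0.4) Hz")
    if (any(lf_amp < 0 | hf_amp < 0 | noise_sd < 0))
      stop("amplitudes and noise_sd must be non-negative")
    if (any(lf_amp + hf_amp + vlf_amp + 4 * noise_sd >= mean_rr))
      stop("amplitudes + noise too large relative to mean_rr; ",
           "non-positive intervals would be likely")
  })
  if (vlf_amp < 0 || vlf_freq <= 0 || vlf_freq >= 0.04)
    stop("vlf_freq must lie in (0, 0.04) Hz and vlf_amp be non-negative")
  if (bout_cv < 0 || bout_cv > 1 || amp_cv < 0 || amp_cv > 1)
    stop("bout_cv and amp_cv must lie in [0, 1]")
  rownames(table) <- table$stage
  structure(list(table = table, vlf_amp = vlf_amp, vlf_freq = vlf_freq,
                 bout_cv = bout_cv, amp_cv = amp_cv),
            class = "stage_hrv_params")
}

#' Generate a synthetic R-peak stream for one night
#'
#' Beat times are built iteratively, `t[k+1] = t[k] + RR(t[k])`, where the
#' instantaneous interval is the stage's baseline plus LF and HF sinusoidal
#' modulation, a shared very-low-frequency wander, and white noise:
#'
#' `RR(t) = mean_rr(stage(t)) + m_lf lf_amp sin(2 pi lf_freq t + phi)
#'        + m_hf hf_amp sin(2 pi hf_freq t + psi)
#'        + vlf_amp sin(2 pi vlf_freq t + theta) + m_n N(0, noise_sd^2)`
#'
#' The phases `phi`, `psi`, `theta` are drawn once per night. The
#' multipliers `m_lf`, `m_hf` (log-scale SD `params$amp_cv`) and `m_n`
#' (log-scale SD `params$bout_cv`) are lognormal and redrawn at every stage
#' visit (bout), modelling the bout-to-bout heterogeneity of autonomic tone
#' that real sleep shows: two wake bouts of the same night differ in their
#' spectral content, not just two stages. The stream spans the full
#' hypnogram.
#'
#' @param hyp micro-coded [hypnogram()].
#' @param params a [stage_hrv_params()].
#' @param seed integer seed for this night.
#' @param participant_id identifier attached to the stream.
#' @return an [rpeak_stream()].
#' @export
generate_rpeaks <- function(hyp, params, seed = 1L,
                            participant_id = "p1") {
  if (!inherits(hyp, "hypnogram") || hyp$scheme != "micro")
    stop("hyp must be a micro-coded hypnogram")
  if (!inherits(params, "stage_hrv_params"))
    stop("params must be stage_hrv_params")
  if (any(hyp$labels == "S4"))
    stop("merge S4 labels before generating RR dynamics")
  tab <- params$table
  n_ep <- length(hyp$labels)
  span <- n_ep * hyp$epoch_s
  # bout index per epoch: a bout is a maximal run of one stage
  runs <- rle(hyp$labels)
  bout_of_epoch <- rep(seq_along(runs$lengths), runs$lengths)
  n_bouts <- length(runs$lengths)
  with_seed(seed, {
    phi <- stats::runif(1, 0, 2 * pi)
    psi <- stats::runif(1, 0, 2 * pi)
    theta <- stats::runif(1, 0, 2 * pi)
    mult <- matrix(exp(stats::rnorm(3L * n_bouts, 0, 1)), nrow = n_bouts)
    mult[, 1:2] <- mult[, 1:2]^params$amp_cv  # lf, hf amplitude multipliers
    mult[, 3] <- mult[, 3]^params$bout_cv     # noise multiplier
    n_guess <- ceiling(span / min(tab$mean_rr)) + 16L
    noise <- stats::rnorm(n_guess, 0, 1)
    times <- numeric(n_guess)
    t <- 0
    k <- 1L
    while (t < span) {
      if (k > length(times)) { # extend buffers (rare)
        noise <- c(noise, stats::rnorm(n_guess, 0, 1))
        times <- c(times, numeric(n_guess))
      }
      times[k] <- t
      ep <- min(n_ep, floor(t / hyp$epoch_s) + 1L)
      st <- hyp$labels[[ep]]
      b <- bout_of_epoch[[ep]]
      rr <- tab[st, "mean_rr"] +
        mult[b, 1L] * tab[st, "lf_amp"] *
          sin(2 * pi * tab[st, "lf_freq"] * t + phi) +
        mult[b, 2L] * tab[st, "hf_amp"] *
          sin(2 * pi * tab[st, "hf_freq"] * t + psi) +
        params$vlf_amp * sin(2 * pi * params$vlf_freq * t + theta) +
        mult[b, 3L] * tab[st, "noise_sd"] * noise[k]
      if (rr <= 0.2)
        stop("generated RR interval <= 0.2 s; parameters too aggressive")
      t <- t + rr
      k <- k + 1L
    }
    rpeak_stream(times[seq_len(k - 1L)], participant_id)
  })
}

#' Generate a full synthetic cohort
#'
#' One hypnogram and R-peak stream per participant. Per-participant seeds
#' derive from `spec$seed` via [split_seed()], so enlarging the cohort never
#' changes already-generated participants.
#'
#' @param spec a [cohort_spec()].
#' @param params a [stage_hrv_params()]; `NULL` skips R-peak generation
#'   (hypnograms only, e.g. for occupancy studies).
#' @return list with elements `spec`, `hypnograms` (list), and `streams`
#'   (list of [rpeak_stream()] or `NULL`).
#' @export
generate_cohort <- function(spec, params = stage_hrv_params()) {
  ids <- sprintf("p%02d", seq_len(spec$n_participants))
  hyps <- lapply(seq_len(spec$n_participants), function(i)
    generate_hypnogram(spec, split_seed(spec$seed, i, 0L)))
  streams <- NULL
  if (!is.null(params)) {
    streams <- lapply(seq_len(spec$n_participants), function(i) {
      h <- hyps[[i]]
      if (any(h$labels == "S4")) h <- merge_s4(h)
      generate_rpeaks(h, params, split_seed(spec$seed, i, 1L), ids[i])
    })
    names(streams) <- ids
  }
  names(hyps) <- ids
  list(spec = spec, hypnograms = hyps, streams = streams)
}

#' Generate the laboratory beat-pair table
#'
#' Emulates the paired ECG-R / BCG-J archive: for each participant,
#' `beats_per` consecutive beats with an R-to-ground-truth-J interval (RGI,
#' ms) drawn from a Gaussian truncated at zero, and a detected-vs-true
#' J-timing error `ep` (ms) drawn zero-mean Gaussian. The defaults give the
#' 27 x 100 = 2700-row table the bound analysis expects. The default RGI and
#' ep spreads are inferred by inverting the half-normal mean relation from
#' the reported mean absolute deviations (|RGI| 7.16 ms -> SD ~ 9 ms; |ep|
#' 8.77 ms -> SD ~ 11 ms); the RGI mean is a typical physiological R-to-J
#' delay and cancels out of the bound.
#'
#' @param n_participants,beats_per table dimensions.
#' @param rgi_mean_ms,rgi_sd_ms RGI distribution (ms).
#' @param ep_sd_ms SD of the detection error (ms).
#' @param seed integer seed.
#' @return tibble with columns `participant_id, beat_index, rgi_ms, ep_ms`.
#' @export
generate_beat_pairs <- function(n_participants = 27L, beats_per = 100L,
                                rgi_mean_ms = 230, rgi_sd_ms = 9,
                                ep_sd_ms = 11, seed = 1L) {
  if (n_participants < 1 || beats_per < 1) stop("counts must be positive")
  if (rgi_sd_ms < 0 || ep_sd_ms < 0) stop("spreads must be non-negative")
  rows <- lapply(seq_len(n_participants), function(i) {
    with_seed(split_seed(seed, i, 2L), {
      rgi <- stats::rnorm(beats_per, rgi_mean_ms, rgi_sd_ms)
      while (any(rgi <= 0))
        rgi[rgi <= 0] <- stats::rnorm(sum(rgi <= 0), rgi_mean_ms, rgi_sd_ms)
      tibble::tibble(
        participant_id = sprintf("lab%02d", i),
        beat_index = seq_len(beats_per),
        rgi_ms = rgi,
        ep_ms = stats::rnorm(beats_per, 0, ep_sd_ms)
      )
    })
  })
  do.call(rbind, rows)
}

#' Write / read the cohort CSV interchange formats
#'
#' `rpeaks.csv`: `participant_id, time_s`; `hypnogram.csv`:
#' `participant_id, epoch_index` (0-based), `stage`;
#' `beat_pairs.csv`: `participant_id, beat_index, rgi_ms, ep_ms`.
#'
#' @param streams list of [rpeak_stream()].
#' @param hyps named list of [hypnogram()].
#' @param pairs beat-pair tibble.
#' @param path output file.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_rpeaks_csv <- function(streams, path) {
  df <- do.call(rbind, lapply(streams, function(s)
    data.frame(participant_id = s$participant_id, time_s = s$times)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_rpeaks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$participant_id), function(d)
    rpeak_stream(sort(d$time_s), d$participant_id[1]))
}

#' @rdname cohort_io
#' @export
write_hypnograms_csv <- function(hyps, path) {
  df <- do.call(rbind, lapply(names(hyps), function(id)
    data.frame(participant_id = id,
               epoch_index = seq_along(hyps[[id]]$labels) - 1L,
               stage = hyps[[id]]$labels)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_hypnograms_csv <- function(path, epoch_s = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$participant_id), function(d)
    hypnogram(d$stage[order(d$epoch_index)], epoch_s = epoch_s))
}

#' @rdname cohort_io
#' @export
write_beat_pairs_csv <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_beat_pairs_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
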