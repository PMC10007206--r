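# Per-epoch HRV features from unevenly sampled heartbeat-interval series.
#
# Each 30-s scoring epoch gets a five-minute analysis window centred on its
# midpoint (90% overlap between successive windows, matching the epoch
# grid). Time-domain features are the windowed mean interval (HR, seconds)
# and interval SD (SDNN); frequency-domain features are LF (0.04-0.15 Hz)
# and HF (0.15-0.4 Hz) band powers of the classical normalized Lomb-Scargle
# periodogram of the mean-subtracted interval series -- the standard
# estimator for unevenly sampled tachograms, avoiding resampling -- plus
# their ratio LFHF and a running-median-smoothed copy MedFiltLFHF.

#' Sliding-window specification for feature extraction
#'
#' @param width_s window length in seconds (multiple of `epoch_s`).
#' @param epoch_s scoring epoch length in seconds; the hop equals one epoch,
#'   i.e. `1 - epoch_s / width_s` fractional overlap (90% at the defaults).
#' @param min_beats minimum intervals a window needs for its spectral
#'   features to be marked valid.
#' @param f_lo,f_hi,f_step Lomb-Scargle evaluation grid (Hz).
#' @param lf_band,hf_band band edges (Hz), half-open `[lo, hi)`.
#' @param medfilt_k running-median kernel for MedFiltLFHF (epochs, odd).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(width_s = 300, epoch_s = 30, min_beats = 60L,
                        f_lo = 0.005, f_hi = 0.5, f_step = 0.0025,
                        lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                        medfilt_k = 5L) {
  if (width_s <= 0 || epoch_s <= 0) stop("window and epoch must be positive")
  if (abs(width_s / epoch_s - round(width_s / epoch_s)) > 1e-9)
    stop("width_s must be a multiple of epoch_s")
  if (f_lo <= 0 || f_step <= 0 || f_hi <= f_lo) stop("invalid frequency grid")
  nf <- floor((f_hi - f_lo) / f_step + 1e-9) + 1L
  structure(list(width_s = width_s, step_s = epoch_s, epoch_s = epoch_s,
                 min_beats = as.integer(min_beats),
                 f_lo = f_lo, f_step = f_step, nf = as.integer(nf),
                 lf_band = lf_band, hf_band = hf_band,
                 medfilt_k = as.integer(medfilt_k)),
            class = "window_spec")
}

#' Analysis window for one epoch
#'
#' Half-open interval of `width_s` seconds centred on the epoch's midpoint,
#' clipped to the record span.
#'
#' @param epoch_index 0-based epoch index.
#' @param spec a [window_spec()].
#' @param record_span `c(start, end)` of the record in seconds.
#' @return named numeric `c(lo, hi, clipped)`; `clipped` is 1 if the window
#'   hit a record boundary.
#' @export
window_for_epoch <- function(epoch_index, spec, record_span) {
  mid <- (epoch_index + 0.5) * spec$epoch_s
  if (mid < record_span[1] || mid > record_span[2])
    stop("epoch midpoint outside the record span")
  lo <- mid - spec$width_s / 2
  hi <- mid + spec$width_s / 2
  clipped <- lo < record_span[1] || hi > record_span[2]
  c(lo = max(lo, record_span[1]), hi = min(hi, record_span[2]),
    clipped = as.numeric(clipped))
}

#' Normalized Lomb-Scargle periodogram of an HBI series
#'
#' @param hbis an [hbi_series()] (or anything with `timestamps` and
#'   `intervals`).
#' @param spec a [window_spec()] supplying the frequency grid.
#' @return tibble with columns `freq_hz`, `power`.
#' @export
ls_periodogram <- function(hbis, spec = window_spec()) {
  p <- ls_periodogram_cpp(hbis$timestamps, hbis$intervals,
                          spec$f_lo, spec$f_step, spec$nf)
  tibble::tibble(freq_hz = spec$f_lo + (seq_len(spec$nf) - 1L) * spec$f_step,
                 power = p)
}

#' Band power of an HBI series
#'
#' Mean normalized Lomb-Scargle ordinate over grid frequencies in
#' `[band[1], band[2])`.
#'
#' @param hbis an [hbi_series()] with at least `min_beats` intervals.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param spec a [window_spec()].
#' @param min_beats minimum intervals required; fewer raises an error (in
#'   the windowed pipeline such windows are flagged invalid instead).
#' @return scalar band power (normalized periodogram units).
#' @export
lomb_band_power <- function(hbis, band, spec = window_spec(),
                            min_beats = spec$min_beats) {
  if (length(hbis$intervals) < min_beats)
    stop("too few intervals (", length(hbis$intervals), " < ", min_beats, ")")
  pg <- ls_periodogram(hbis, spec)
  sel <- pg$freq_hz >= band[1] - 1e-9 & pg$freq_hz < band[2] - 1e-9
  if (!any(sel)) stop("band contains no grid frequencies")
  mean(pg$power[sel])
}

#' Per-epoch HRV feature matrix for one participant at one jitter level
#'
#' For every epoch of the hypnogram: HR (mean interval, s) and SDNN
#' (interval SD, s) over the centred window, LF and HF Lomb-Scargle band
#' powers, LFHF = LF/HF, and MedFiltLFHF, a running median (default kernel
#' 5 epochs, edge-truncated) of the LFHF column. Windows with fewer than
#' `min_beats` intervals are flagged `valid = FALSE`; clipped boundary
#' windows are flagged but remain valid if they hold enough beats.
#'
#' @param hbis an [hbi_series()] for the night.
#' @param hyp the night's [hypnogram()] (defines the epoch grid).
#' @param spec a [window_spec()].
#' @return tibble with one row per epoch: `epoch_index` (0-based), `level`,
#'   `n_beats`, `clipped`, `HR`, `SDNN`, `LF`, `HF`, `LFHF`, `MedFiltLFHF`,
#'   `valid`.
#' @export
compute_features <- function(hbis, hyp, spec = window_spec()) {
  if (length(hbis$intervals) == 0) stop("empty HBI series")
  if (abs(hyp$epoch_s - spec$epoch_s) > 1e-9)
    stop("hypnogram and window spec disagree on epoch length")
  n_ep <- length(hyp$labels)
  span <- c(0, n_ep * hyp$epoch_s)
  mids <- (seq_len(n_ep) - 0.5) * hyp$epoch_s
  lo <- pmax(mids - spec$width_s / 2, span[1])
  hi <- pmin(mids + spec$width_s / 2, span[2])
  clipped <- (mids - spec$width_s / 2 < span[1]) |
             (mids + spec$width_s / 2 > span[2])
  m <- window_hrv_cpp(hbis$timestamps, hbis$intervals, lo, hi,
                      spec$f_lo, spec$f_step, spec$nf,
                      spec$lf_band[1], spec$lf_band[2],
                      spec$hf_band[1], spec$hf_band[2])
  lfhf <- ifelse(is.na(m[, "hf"]) | m[, "hf"] <= 0, NA_real_,
                 m[, "lf"] / m[, "hf"])
  tibble::tibble(
    epoch_index = seq_len(n_ep) - 1L,
    level = hbis$level,
    n_beats = as.integer(m[, "n_beats"]),
    clipped = clipped,
    HR = m[, "mean_s"],
    SDNN = m[, "sd_s"],
    LF = m[, "lf"],
    HF = m[, "hf"],
    LFHF = lfhf,
    MedFiltLFHF = running_median(lfhf, spec$medfilt_k),
    valid = as.integer(m[, "n_beats"]) >= spec$min_beats
  )
}

#' Feature stack across jitter levels for one participant
#'
#' Recomputes the jittered stream of each requested ladder level (seeded, so
#' results are reproducible) and extracts the per-epoch feature matrix at
#' each; level 0 is the unjittered baseline.
#'
#' @param stream baseline [rpeak_stream()].
#' @param hyp the night's [hypnogram()].
#' @param ladder a [build_ladder()] result.
#' @param participant_index 1-based index in the ladder's cohort.
#' @param levels integer vector of levels (0 = baseline) to compute.
#' @param spec a [window_spec()].
#' @return tibble: feature matrix rows for all requested levels.
#' @export
feature_stack <- function(stream, hyp, ladder, participant_index,
                          levels = 0:ladder$n_levels, spec = window_spec()) {
  do.call(rbind, lapply(levels, function(lev) {
    s <- ladder_stream(stream, ladder, participant_index, lev)
    compute_features(hbis_from_peaks(s, lev), hyp, spec)
  }))
}

# Feature column names in canonical order.
HRV_FEATURES <- c("HR", "SDNN", "LF", "HF", "LFHF", "MedFiltLFHF")
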