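# Conservative upper bound on total BCG-vs-ECG beat timing error.
#
# The total R-to-detected-J error decomposes as e_T = RGI + e_p (R to
# ground-truth-J interval plus J detection error), so by the triangle
# inequality |e_T| <= |RGI| + |e_p|. Because HRV features are insensitive
# to a constant timing offset, only the deviation of each RGI from its
# participant's mean matters: |RGI| here always means the per-beat absolute
# deviation from the participant-wise mean RGI.

#' Per-beat absolute RGI jitter
#'
#' For each beat j of participant i: `|RGI_{j,i} - mean_i(RGI)|`, with the
#' mean taken over that participant's beats only (never pooled), in ms.
#'
#' @param table beat-pair tibble with columns `participant_id, rgi_ms`.
#' @return numeric vector, one value per row of `table` (row order
#'   preserved).
#' @export
rgi_jitter <- function(table) {
  if (nrow(table) == 0) stop("empty beat-pair table")
  cnt <- table(table$participant_id)
  if (any(cnt < 2))
    stop("every participant needs >= 2 beats to centre RGIs: ",
         paste(names(cnt)[cnt < 2], collapse = ","))
  mu <- stats::ave(table$rgi_ms, table$participant_id)
  abs(table$rgi_ms - mu)
}

#' Summary statistics of the timing-error bound
#'
#' Per beat, the bound is `|RGI| + |e_p|`; mean, median, min and max are
#' taken over all beats pooled (per-beat sums first, then the statistic --
#' medians and extremes are not additive across components).
#'
#' @param table beat-pair tibble (`participant_id, beat_index, rgi_ms,
#'   ep_ms`).
#' @return object of class `bound_summary`: a tibble with rows `|RGI|`,
#'   `|ep|`, `|RGI|+|ep|` and columns `mean_ms, median_ms, min_ms, max_ms`,
#'   plus attribute `n_beats`.
#' @export
total_bound <- function(table) {
  if (nrow(table) == 0) stop("empty beat-pair table")
  rgi <- rgi_jitter(table)
  ep <- abs(table$ep_ms)
  tot <- rgi + ep
  stat <- function(x) c(mean(x), stats::median(x), min(x), max(x))
  m <- rbind(`|RGI|` = stat(rgi), `|ep|` = stat(ep),
             `|RGI|+|ep|` = stat(tot))
  out <- tibble::tibble(quantity = rownames(m),
                        mean_ms = unname(m[, 1]), median_ms = unname(m[, 2]),
                        min_ms = unname(m[, 3]), max_ms = unname(m[, 4]))
  structure(out, n_beats = nrow(table), class = c("bound_summary",
                                                  class(out)))
}

#' Project a timing-error bound onto an ensemble error curve
#'
#' Linear interpolation of the ensemble mean staging error at
#' `MAE = bound_ms`: the staging error a system operating at that timing
#' error could be expected to incur.
#'
#' @param bound_ms timing-error bound (ms); must lie inside the curve's MAE
#'   range.
#' @param curve an [ensemble_curve()] tibble (`mae_ms`, `mean`).
#' @return projected error (%).
#' @export
project_error <- function(bound_ms, curve) {
  rng <- range(curve$mae_ms)
  if (bound_ms < rng[1] || bound_ms > rng[2])
    stop("bound ", bound_ms, " ms outside the curve range [",
         round(rng[1], 2), ", ", round(rng[2], 2), "] ms")
  stats::approx(curve$mae_ms, curve$mean, xout = bound_ms, ties = mean)$y
}

#' Serialize a bound summary as JSON
#'
#' @param summary a [total_bound()] result.
#' @param path output path.
#' @export
write_bound_json <- function(summary, path) {
  x <- lapply(seq_len(nrow(summary)), function(i) list(
    mean_ms = summary$mean_ms[i], median_ms = summary$median_ms[i],
    min_ms = summary$min_ms[i], max_ms = summary$max_ms[i]))
  names(x) <- summary$quantity
  x$n_beats <- attr(summary, "n_beats")
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
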