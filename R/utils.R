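#' Derive a child RNG seed from a base seed and integer coordinates
#'
#' All stochastic steps in the pipeline draw from seeds produced by this
#' hash, keyed on (base seed, participant index, jitter level, ...). Splitting
#' hierarchically means adding participants or levels to a run never perturbs
#' the draws of existing ones, and every artifact is reproducible from the
#' single run seed.
#'
#' The hash is a multiplicative congruential mix modulo the Mersenne prime
#' 2^31 - 1, computed in doubles (all intermediates stay below 2^53, so the
#' arithmetic is exact).
#'
#' @param seed base integer seed.
#' @param ... further non-negative integer coordinates (participant index,
#'   level, stage index, ...).
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
split_seed <- function(seed, ...) {
  ids <- c(as.numeric(seed), as.numeric(c(...)))
  stopifnot(all(is.finite(ids)))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (v in ids) {
    h <- (h * 48271 + abs(v) + 1) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Edge-truncated running median (window shrinks at the series ends), NA-aware.
running_median <- function(x, k = 5L) {
  stopifnot(k >= 1L, k %% 2L == 1L)
  h <- k %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
  }, numeric(1))
}
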