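# Hypnogram cleaning and relabeling: merge the rare non-standard S4 label
# into S3, absorb short glitch runs into their neighbours, and collapse the
# five-class micro scheme to the three-class macro scheme.

#' Merge S4 labels into S3
#'
#' S4 is a non-standard, rarely used deep-sleep label; it is folded into S3
#' so downstream analysis sees the five-class micro alphabet.
#'
#' @param hyp micro-coded [hypnogram()].
#' @return hypnogram of the same length with every S4 replaced by S3.
#' @export
merge_s4 <- function(hyp) {
  if (!inherits(hyp, "hypnogram") || hyp$scheme != "micro")
    stop("merge_s4 expects a micro-coded hypnogram")
  labs <- hyp$labels
  labs[labs == "S4"] <- "S3"
  hypnogram(labs, hyp$epoch_s, "micro")
}

#' Merge short stage runs into their preceding stage
#'
#' Scoring glitches show up as stage runs only an epoch or two long,
#' typically with the same stage before and after. Scanning left to right,
#' any maximal run shorter than `min_epochs` is relabeled to the preceding
#' (already cleaned) run's stage; a short leading run, having no
#' predecessor, takes the following run's stage. Merging can fuse adjacent
#' runs into a new short run, so the scan repeats until a fixed point.
#'
#' @param hyp micro-coded [hypnogram()] (S4 already merged).
#' @param min_epochs minimum run length to survive, in epochs.
#' @return hypnogram of identical length with no run shorter than
#'   `min_epochs` (unless the whole night is one short run).
#' @export
merge_short_runs <- function(hyp, min_epochs = 4L) {
  if (!inherits(hyp, "hypnogram")) stop("hyp must be a hypnogram")
  if (min_epochs < 1) stop("min_epochs must be >= 1")
  labs <- hyp$labels
  if (length(labs) < min_epochs) {
    warning("hypnogram shorter than min_epochs; returned unchanged")
    return(hyp)
  }
  repeat {
    r <- rle(labs)
    if (length(r$lengths) == 1L) break
    short <- which(r$lengths < min_epochs)
    if (length(short) == 0L) break
    i <- short[1L]
    r$values[i] <- if (i == 1L) r$values[2L] else r$values[i - 1L]
    labs <- inverse.rle(r)
  }
  hypnogram(labs, hyp$epoch_s, hyp$scheme)
}

#' Collapse a cleaned micro hypnogram to the macro scheme
#'
#' S1, S2 and S3 map to NREM; W to Wake; R to REM.
#'
#' @param hyp cleaned micro-coded [hypnogram()] (no S4).
#' @return macro-coded hypnogram of the same length.
#' @export
to_macro <- function(hyp) {
  if (!inherits(hyp, "hypnogram") || hyp$scheme != "micro")
    stop("to_macro expects a micro-coded hypnogram")
  map <- c(W = "Wake", S1 = "NREM", S2 = "NREM", S3 = "NREM", R = "REM")
  bad <- setdiff(unique(hyp$labels), names(map))
  if (length(bad))
    stop("unknown labels for macro mapping: ", paste(bad, collapse = ","))
  hypnogram(unname(map[hyp$labels]), hyp$epoch_s, "macro")
}

#' Standard label cleaning for one night
#'
#' S4 merge followed by short-run absorption; optionally collapse to macro.
#'
#' @param hyp raw micro-coded [hypnogram()].
#' @param scheme `"micro"` or `"macro"`.
#' @param min_epochs passed to [merge_short_runs()].
#' @return cleaned hypnogram in the requested scheme.
#' @export
clean_hypnogram <- function(hyp, scheme = c("micro", "macro"),
                            min_epochs = 4L) {
  scheme <- match.arg(scheme)
  out <- merge_short_runs(merge_s4(hyp), min_epochs)
  if (scheme == "macro") out <- to_macro(out)
  out
}
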