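# End-to-end orchestration: simulate -> clean labels -> jitter ladder ->
# HRV features -> staging evaluation -> timing-error bound -> report, driven
# by a single config (YAML/JSON) and one run seed. Every stage writes its
# outputs under the run directory and can be re-run from cached upstream
# artifacts; a manifest records config, seeds and output paths.

default_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_participants = 10L, epoch_s = 30,
                  duration_mean_h = 8.43, duration_sd_h = 0.5,
                  min_duration_h = 6,
                  stage_props = list(W = 0.300, S1 = 0.026, S2 = 0.411,
                                     S3 = 0.116, R = 0.147),
                  mean_dwell_epochs = list(W = 10, S1 = 6, S2 = 16,
                                           S3 = 9, R = 12),
                  short_run_rate = 0),
    ladder = list(n_levels = 97L, target_mae_ms = 60),
    features = list(width_s = 300, min_beats = 60L, medfilt_k = 5L,
                    lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4)),
    evaluate = list(levels = NULL, k_folds = 10L, knn_k = 10L,
                    min_epochs = 4L, schemes = c("micro", "macro"),
                    feature_subsets = "all"),
    beat_pairs = list(n_participants = 27L, beats_per = 100L,
                      rgi_mean_ms = 230, rgi_sd_ms = 9, ep_sd_ms = 11)
  )
}

#' Read and validate a pipeline configuration
#'
#' The config file (YAML or JSON) mirrors the field names of
#' [cohort_spec()], [build_ladder()], [window_spec()] and
#' [generate_beat_pairs()]; any key absent falls back to the package
#' default, and any unknown key is an error naming the key.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list merged over the file (e.g. from a script's
#'   arguments).
#' @return validated config list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  merge_into <- function(base, new, prefix = "") {
    for (k in names(new)) {
      key <- paste0(prefix, k)
      if (!k %in% names(base))
        stop("unknown config key: ", key)
      if (is.list(base[[k]]) && is.list(new[[k]]) &&
          !is.null(names(base[[k]])))
        base[[k]] <- merge_into(base[[k]], new[[k]], paste0(key, "."))
      else base[[k]] <- new[[k]]
    }
    base
  }
  cfg <- merge_into(cfg, user)
  cfg <- merge_into(cfg, overrides)
  sp <- unlist(cfg$cohort$stage_props)
  if (abs(sum(sp) - 1) > 1e-9)
    stop("config key cohort.stage_props must sum to 1 (got ", sum(sp), ")")
  if (is.null(cfg$evaluate$levels))
    cfg$evaluate$levels <- 0:cfg$ladder$n_levels
  cfg
}

config_cohort_spec <- function(cfg) {
  cohort_spec(
    n_participants = cfg$cohort$n_participants,
    epoch_s = cfg$cohort$epoch_s,
    duration_mean_h = cfg$cohort$duration_mean_h,
    duration_sd_h = cfg$cohort$duration_sd_h,
    min_duration_h = cfg$cohort$min_duration_h,
    stage_props = unlist(cfg$cohort$stage_props),
    mean_dwell_epochs = unlist(cfg$cohort$mean_dwell_epochs),
    short_run_rate = cfg$cohort$short_run_rate,
    seed = cfg$seed)
}

config_window_spec <- function(cfg) {
  window_spec(width_s = cfg$features$width_s, epoch_s = cfg$cohort$epoch_s,
              min_beats = cfg$features$min_beats,
              lf_band = cfg$features$lf_band,
              hf_band = cfg$features$hf_band,
              medfilt_k = cfg$features$medfilt_k)
}

#' Run the full simulation study
#'
#' Executes the pipeline stages in order, writing machine-readable outputs
#' under `out_dir`: `rpeaks.csv`, `hypnogram.csv`, `beat_pairs.csv`,
#' `ladder.json`, `features.csv`, `results.csv`, `bound_summary.json`, the
#' report tables, and `manifest.json`. A stage whose outputs already exist
#' is skipped unless `force = TRUE`; skipped stages' outputs are loaded from
#' disk, so a run is resumable and deleting a downstream artifact re-derives
#' it identically from the cached upstream ones.
#'
#' @param config config list from [read_config()], or a path to a config
#'   file.
#' @param out_dir output directory (created if missing).
#' @param force recompute every stage even if outputs exist.
#' @param quiet suppress per-stage progress messages.
#' @return the manifest (invisibly), also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = NULL, out_dir = "results", force = FALSE,
                         quiet = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else
    if (is.null(config)) read_config() else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  say <- function(...) if (!quiet) message("[jitterhrv] ", ...)
  t_start <- Sys.time()

  spec <- config_cohort_spec(cfg)
  params <- stage_hrv_params()
  wspec <- config_window_spec(cfg)

  # -- simulate -------------------------------------------------------------
  if (force || !file.exists(pth("rpeaks.csv"))) {
    say("simulate: ", spec$n_participants, " nights")
    cohort <- generate_cohort(spec, params)
    write_rpeaks_csv(cohort$streams, pth("rpeaks.csv"))
    write_hypnograms_csv(cohort$hypnograms, pth("hypnogram.csv"))
    write_beat_pairs_csv(do.call(generate_beat_pairs,
                                 c(cfg$beat_pairs, list(seed = cfg$seed))),
                         pth("beat_pairs.csv"))
  } else say("simulate: cached")
  streams <- read_rpeaks_csv(pth("rpeaks.csv"))
  hyps <- read_hypnograms_csv(pth("hypnogram.csv"), spec$epoch_s)
  streams <- streams[names(hyps)]

  # -- ladder ---------------------------------------------------------------
  if (force || !file.exists(pth("ladder.json"))) {
    say("ladder: ", cfg$ladder$n_levels, " levels -> ",
        cfg$ladder$target_mae_ms, " ms")
    ladder <- build_ladder(streams, cfg$ladder$n_levels,
                           cfg$ladder$target_mae_ms, seed = cfg$seed)
    write_ladder_json(ladder, pth("ladder.json"))
  } else say("ladder: cached")
  ladder <- read_ladder_json(pth("ladder.json"))

  # -- features -------------------------------------------------------------
  levels <- cfg$evaluate$levels
  if (force || !file.exists(pth("features.csv"))) {
    say("features: ", length(levels), " levels x ", length(streams),
        " participants")
    feats <- do.call(rbind, lapply(seq_along(streams), function(i) {
      st <- feature_stack(streams[[i]], hyps[[i]], ladder, i, levels, wspec)
      st$participant_id <- names(streams)[i]
      st
    }))
    utils::write.csv(feats, pth("features.csv"), row.names = FALSE)
  } else say("features: cached")
  feats <- tibble::as_tibble(utils::read.csv(pth("features.csv")))

  # -- evaluate -------------------------------------------------------------
  if (force || !file.exists(pth("results.csv"))) {
    stacks <- split(feats, feats$participant_id)[names(streams)]
    res <- list()
    for (scheme in cfg$evaluate$schemes)
      for (fs in cfg$evaluate$feature_subsets) {
        say("evaluate: ", scheme, " / ", fs)
        r <- evaluate_cohort(stacks, hyps, ladder, levels, scheme, fs,
                             cfg$evaluate$k_folds, cfg$evaluate$knn_k,
                             seed = cfg$seed,
                             min_epochs = cfg$evaluate$min_epochs)
        if (identical(fs, "all")) {
          pooled <- tryCatch(aggregate_confusion(attr(r, "confusions")),
                             error = function(e) NULL)
          if (!is.null(pooled))
            utils::write.csv(as.data.frame.matrix(pooled),
                             pth(paste0("confusion_", scheme, ".csv")))
        }
        res[[length(res) + 1L]] <- r
      }
    utils::write.csv(do.call(rbind, res), pth("results.csv"),
                     row.names = FALSE)
  } else say("evaluate: cached")
  results <- tibble::as_tibble(utils::read.csv(pth("results.csv")))

  # -- bound ----------------------------------------------------------------
  pairs <- read_beat_pairs_csv(pth("beat_pairs.csv"))
  bs <- total_bound(pairs)
  write_bound_json(bs, pth("bound_summary.json"))

  report_tables(results, bs, out_dir, say)

  manifest <- list(
    package_version = as.character(utils::packageVersion("jitterhrv")),
    created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    seed = cfg$seed,
    config = cfg,
    outputs = union(list.files(out_dir), "manifest.json"))
  jsonlite::write_json(manifest, pth("manifest.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  missing <- setdiff(c("rpeaks.csv", "hypnogram.csv", "beat_pairs.csv",
                       "ladder.json", "features.csv", "results.csv",
                       "bound_summary.json"), manifest$outputs)
  if (length(missing))
    stop("pipeline finished but outputs are missing: ",
         paste(missing, collapse = ","))
  invisible(manifest)
}

# Summary tables: terminal errors per scheme, sensitivity slopes per
# feature x scheme (when single-feature results exist), ensemble curves,
# and the bound projection.
report_tables <- function(results, bound_summary, out_dir, say = message) {
  pth <- function(f) file.path(out_dir, f)
  all_res <- results[results$feature_subset == "all", ]
  curves <- NULL
  e0emax <- NULL
  for (scheme in unique(all_res$scheme)) {
    d <- all_res[all_res$scheme == scheme, ]
    ec <- ensemble_curve(d)
    ec$scheme <- scheme
    curves <- rbind(curves, ec)
    lv <- range(d$level)
    e0emax <- rbind(e0emax, data.frame(
      scheme = scheme,
      e0_pct = ec$mean[ec$level == lv[1]],
      emax_pct = ec$mean[ec$level == lv[2]]))
  }
  utils::write.csv(curves, pth("ensemble_curves.csv"), row.names = FALSE)
  utils::write.csv(e0emax, pth("e0_emax.csv"), row.names = FALSE)

  single <- results[results$feature_subset != "all", ]
  if (nrow(single) > 0) {
    rows <- list()
    for (scheme in unique(single$scheme))
      for (fs in unique(single$feature_subset)) {
        d <- single[single$scheme == scheme & single$feature_subset == fs, ]
        sl <- vapply(split(d, d$participant_id), function(p)
          as.numeric(sensitivity_slope(p$mae_ms / 1000, p$error_pct)),
          numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = scheme, feature = fs, slope_pct_per_s = mean(sl))
      }
    utils::write.csv(do.call(rbind, rows), pth("slopes.csv"),
                     row.names = FALSE)
  }

  b <- bound_summary$mean_ms[bound_summary$quantity == "|RGI|+|ep|"]
  proj <- lapply(split(curves, curves$scheme), function(cc)
    tryCatch(project_error(b, cc), error = function(e) NA_real_))
  jsonlite::write_json(list(bound_ms = b, projected_error_pct = proj),
                       pth("projection.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(NULL)
}
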