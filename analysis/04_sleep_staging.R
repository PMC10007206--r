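#!/usr/bin/env Rscript
# Stage 4: sleep-stage classification across jitter severities.
#
# Per participant and level: stratified 10-fold cross-validated SVM
# (Gaussian kernel, one-vs-one multiclass) and kNN on the per-epoch HRV
# features against the cleaned stage labels, under both the five-class
# micro and three-class macro schemes. Outputs: per-cell results, ensemble
# error curves, kNN-based Bayes lower bounds, per-feature sensitivity
# slopes, and the pooled baseline confusion matrix.

library(jitterhrv)

out_dir <- "results"
SEED <- 1L
hyps <- read_hypnograms_csv(file.path(out_dir, "hypnogram.csv"))
ladder <- read_ladder_json(file.path(out_dir, "ladder.json"))
feats <- read.csv(file.path(out_dir, "features.csv"))
stacks <- split(feats, feats$participant_id)[names(hyps)]
LEVELS <- sort(unique(feats$level))
SLOPE_LEVELS <- LEVELS[seq(1, length(LEVELS), by = 2)]

all_res <- list()
for (scheme in c("micro", "macro")) {
  cat("evaluating", scheme, "(all features) ...\n")
  r <- evaluate_cohort(stacks, hyps, ladder, LEVELS, scheme, "all",
                       seed = SEED)
  conf <- aggregate_confusion(attr(r, "confusions"))
  cat(sprintf("  baseline confusion pooled over %d participants (%d excluded)\n",
              attr(conf, "n_used"), attr(conf, "n_excluded")))
  write.csv(as.data.frame.matrix(conf),
            file.path(out_dir, paste0("confusion_", scheme, ".csv")))
  all_res[[scheme]] <- r
  for (f in c("HR", "SDNN", "LF", "HF", "LFHF", "MedFiltLFHF")) {
    cat("evaluating", scheme, "/", f, "...\n")
    all_res[[paste(scheme, f)]] <-
      evaluate_cohort(stacks, hyps, ladder, SLOPE_LEVELS, scheme, f,
                      seed = SEED)
  }
}
results <- do.call(rbind, all_res)
write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)

# ensemble curves + terminal errors
for (scheme in c("micro", "macro")) {
  ec <- ensemble_curve(all_res[[scheme]])
  write.csv(ec, file.path(out_dir, paste0("curve_", scheme, ".csv")),
            row.names = FALSE)
  cat(sprintf("%s: E0 = %.1f%%, Emax = %.1f%% at %.0f ms MAE\n", scheme,
              ec$mean[1], tail(ec$mean, 1), tail(ec$mae_ms, 1)))
}

# sensitivity slopes (pp of error per second of HBI MAE)
slopes <- do.call(rbind, lapply(c("micro", "macro"), function(scheme)
  do.call(rbind, lapply(c("HR", "SDNN", "LF", "HF", "LFHF", "MedFiltLFHF"),
    function(f) {
      d <- all_res[[paste(scheme, f)]]
      sl <- vapply(split(d, d$participant_id), function(p)
        as.numeric(sensitivity_slope(p$mae_ms / 1000, p$error_pct)),
        numeric(1))
      data.frame(scheme = scheme, feature = f,
                 slope_pct_per_s = mean(sl),
                 slope_se = sd(sl) / sqrt(length(sl)))
    }))))
write.csv(slopes, file.path(out_dir, "slopes.csv"), row.names = FALSE)
cat("sensitivity slopes (%/s, mean +/- SE over participants):\n")
print(slopes, digits = 3)
for (scheme in c("micro", "macro")) {
  d <- slopes[slopes$scheme == scheme, ]
  cat(sprintf("%s: smallest slope %s (%.1f +/- %.1f)\n", scheme,
              d$feature[which.min(d$slope_pct_per_s)],
              min(d$slope_pct_per_s), d$slope_se[which.min(d$slope_pct_per_s)]))
}
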