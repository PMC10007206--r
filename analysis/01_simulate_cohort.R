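#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study material.
#
# Two artifacts: (a) a sleep cohort -- one hypnogram (30-s epochs) and one
# ECG R-peak stream per participant, with stage-dependent RR dynamics; and
# (b) the laboratory-style beat-pair table (27 participants x 100 paired
# ECG-R / BCG-J beats) that feeds the timing-error bound.
#
# The cohort statistics are also checked here at the full 50-night scale;
# the downstream classification stages use a 10-night subset to keep the
# whole workflow at desk scale.

library(jitterhrv)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
N_DOWNSTREAM <- 10L # nights carried into stages 2-4
SEED <- 1L

# -- 50-night occupancy / duration check -----------------------------------
spec50 <- cohort_spec(n_participants = 50L, seed = SEED)
hyps50 <- generate_cohort(spec50, params = NULL)$hypnograms
labs <- unlist(lapply(hyps50, `[[`, "labels"))
occ <- 100 * prop.table(table(factor(labs, c("W", "S1", "S2", "S3", "R"))))
hours <- vapply(hyps50, function(h) length(h$labels) * 30 / 3600, numeric(1))
cat("50-night cohort: pooled stage occupancy (%)\n")
print(round(occ, 1))
cat(sprintf("mean night length %.2f h (sd %.2f)\n", mean(hours), sd(hours)))
write.csv(data.frame(stage = names(occ), occupancy_pct = as.numeric(occ)),
          file.path(out_dir, "cohort_occupancy.csv"), row.names = FALSE)

# -- downstream cohort with R-peak streams ---------------------------------
spec <- cohort_spec(n_participants = N_DOWNSTREAM, seed = SEED)
cohort <- generate_cohort(spec, stage_hrv_params())
write_hypnograms_csv(cohort$hypnograms, file.path(out_dir, "hypnogram.csv"))
write_rpeaks_csv(cohort$streams, file.path(out_dir, "rpeaks.csv"))
cat(sprintf("wrote %d nights (%.1f-%.1f h) to %s\n", N_DOWNSTREAM,
            min(hours[1:N_DOWNSTREAM]), max(hours[1:N_DOWNSTREAM]), out_dir))

# -- laboratory beat-pair table --------------------------------------------
pairs <- generate_beat_pairs(seed = SEED)
write_beat_pairs_csv(pairs, file.path(out_dir, "beat_pairs.csv"))
cat(sprintf("wrote beat-pair table: %d rows (%d participants x %d beats)\n",
            nrow(pairs), length(unique(pairs$participant_id)),
            max(pairs$beat_index)))
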