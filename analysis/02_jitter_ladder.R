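#!/usr/bin/env Rscript
# Stage 2: build the jitter severity ladder.
#
# Each level perturbs every R-peak time with zero-mean Gaussian jitter; the
# ladder's 97 standard deviations are placed so the top level's pooled mean
# absolute HBI error lands on 60 ms (the closed form MAE = 2 sigma / sqrt(pi)
# gives the placement; one rescaling step absorbs Monte-Carlo error).

library(jitterhrv)

out_dir <- "results"
SEED <- 1L
streams <- read_rpeaks_csv(file.path(out_dir, "rpeaks.csv"))

ladder <- build_ladder(streams, n_levels = 97L, target_mae_ms = 60,
                       seed = SEED)
write_ladder_json(ladder, file.path(out_dir, "ladder.json"))

cat(sprintf("ladder: %d levels, sigma %.2f..%.2f ms\n", ladder$n_levels,
            ladder$sigmas_ms[1], max(ladder$sigmas_ms)))
cat(sprintf("pooled MAE at top level: %.2f ms (target %.0f)\n",
            tail(ladder$pooled_mae_ms, 1), ladder$target_mae_ms))
cat(sprintf("closed-form check at sigma=%.1f ms: expected %.2f, realized %.2f\n",
            ladder$sigmas_ms[50], 2 * ladder$sigmas_ms[50] / sqrt(pi),
            ladder$pooled_mae_ms[50]))

curve <- data.frame(level = seq_len(ladder$n_levels),
                    sigma_ms = ladder$sigmas_ms,
                    pooled_mae_ms = ladder$pooled_mae_ms)
write.csv(curve, file.path(out_dir, "ladder_curve.csv"), row.names = FALSE)
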