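#!/usr/bin/env Rscript
# Stage 5: the conservative BCG timing-error bound and its projection.
#
# The total R-to-detected-J timing error decomposes as e_T = RGI + e_p; by
# the triangle inequality |e_T| <= |RGI| + |e_p|, where |RGI| is each
# beat's absolute deviation from its participant's mean R-to-J interval
# (constant offsets are invisible to HRV features). Summing the per-beat
# components bounds the heartbeat-interval MAE a BCG system would add, and
# interpolating the stage-4 error curves at that bound projects the
# staging error such a system could expect.

library(jitterhrv)

out_dir <- "results"
pairs <- read_beat_pairs_csv(file.path(out_dir, "beat_pairs.csv"))
bs <- total_bound(pairs)
write_bound_json(bs, file.path(out_dir, "bound_summary.json"))
cat(sprintf("bound summary over %d beats (ms):\n", attr(bs, "n_beats")))
print(as.data.frame(bs), digits = 4)

bound <- bs$mean_ms[bs$quantity == "|RGI|+|ep|"]
for (scheme in c("micro", "macro")) {
  f <- file.path(out_dir, paste0("curve_", scheme, ".csv"))
  if (!file.exists(f)) { cat("no curve for", scheme, "- run stage 4\n"); next }
  curve <- read.csv(f)
  cat(sprintf("%s: projected staging error at the %.1f ms bound = %.1f%% (E0 %.1f%%)\n",
              scheme, bound, project_error(bound, curve), curve$mean[1]))
}
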