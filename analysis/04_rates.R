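#!/usr/bin/env Rscript
# Stage 4 -- report-aligned microsaccade rate dynamics.
#
# Aligns detected event onsets to the perceptual report, estimates the
# rate with the causal kernel per participant, normalizes baselines
# across participants, and writes the pooled normalized curve. The
# signature feature is a rate dip just before the report.

suppressPackageStartupMessages(library(fixfill))

out <- "results/analysis"
trials <- utils::read.csv(file.path(out, "trials.csv"))
metrics <- read_metrics_csv(file.path(out, "metrics.csv"))
events <- read_events_csv(file.path(out, "events.csv"))

dir.create(file.path(out, "rates"), showWarnings = FALSE)
curves <- list()
for (id in unique(trials$participant)) {
  idx <- which(trials$participant == id & !metrics$excluded)
  onsets <- lapply(idx, function(i) {
    sel <- events$trial == i
    events$onset_ms[sel] - trials$ft_s[i] * 1000
  })
  cv <- causal_rate(onsets, trials$ft_s[idx] * 1000)
  utils::write.csv(as.data.frame(cv),
                   file.path(out, "rates", paste0(id, ".csv")),
                   row.names = FALSE)
  curves[[id]] <- cv
}
norm <- baseline_normalize(curves)
pooled <- norm$curves[[1]]
pooled$rate_hz <- rowMeans(sapply(norm$curves, function(cv) cv$rate_hz))
utils::write.csv(as.data.frame(pooled),
                 file.path(out, "rates", "pooled_normalized.csv"),
                 row.names = FALSE)

base <- norm$grand_baseline
dip <- min(pooled$rate_hz[pooled$time_ms >= -1500], na.rm = TRUE)
dip_t <- pooled$time_ms[which.min(replace(pooled$rate_hz,
                                          pooled$time_ms < -1500, Inf))]
cat(sprintf("Grand baseline %.2f Hz; pre-report minimum %.2f Hz (%.0f%% of baseline) at %d ms.\n",
            base, dip, 100 * dip / base, dip_t))
cat("A minimum well below baseline in the final second reflects the\n")
cat("generator's pre-report suppression of event placement.\n")
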