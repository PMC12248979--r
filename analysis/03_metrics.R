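#!/usr/bin/env Rscript
# Stage 3 -- trial-level oculomotor and perceptual metrics.
#
# Re-reads the traces, assembles per-trial metrics (filling-in time,
# microsaccade presence/count/rate, blink count, retinal-slip drift,
# immobilization time) and applies the exclusion rules, reporting the
# exclusion ledger.

suppressPackageStartupMessages(library(fixfill))

out <- "results/analysis"
trials <- utils::read.csv(file.path(out, "trials.csv"))

traces <- lapply(seq_len(nrow(trials)), function(i)
  read_gaze_tsv(file.path(out, "traces", sprintf("trial_%04d.tsv", i))))
summ <- summarize_trials(list(trials = trials, traces = traces))
write_metrics_csv(summ$metrics, file.path(out, "metrics.csv"))

m <- summ$metrics
tab <- table(m$exclusion_reason)
cat(sprintf("Metrics for %d trials; %d retained.\n", nrow(m),
            sum(!m$excluded)))
cat("Exclusions:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
cat(sprintf("Mean ocular drift %.2f deg/s; %.1f%% of trials with microsaccades; median immobilization %.0f ms.\n",
            mean(m$ocular_drift, na.rm = TRUE),
            100 * mean(m$ms_presence),
            stats::median(m$immobilization_ms, na.rm = TRUE)))
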