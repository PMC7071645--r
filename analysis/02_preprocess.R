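#!/usr/bin/env Rscript
# Stage 2: probe variation filter. Probes whose beta range across samples
# is below 0.10 are excluded from the EWAS (they are kept in a separate
# table for candidate-probe replication).

source("analysis/_common.R")

co <- study_cohorts()
filt <- probe_range_filter(co$blood$beta, min_range = 0.10)
rep <- filt$report

cat(sprintf("input probes:          %d\n", rep$n_input))
cat(sprintf("excluded (range<0.10): %d (%.1f%%)\n", rep$n_excluded_low_range,
            100 * rep$n_excluded_low_range / rep$n_input))
cat(sprintf("retained for EWAS:     %d\n", rep$n_retained))

utils::write.csv(
  data.frame(probe_id = names(rep$range), beta_range = unname(rep$range),
             retained = names(rep$range) %in% filt$retained),
  file.path(results_dir(), "filter_report.csv"), row.names = FALSE)
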