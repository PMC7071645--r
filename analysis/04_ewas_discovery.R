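#!/usr/bin/env Rscript
# Stage 4: discovery EWAS. Per-probe moderated linear models of M-values on
# case status, adjusting for age, sex, ancestry PCs, estimated cell
# fractions and the smoking score; BH-adjusted p-values over the filtered
# probe set; genomic inflation as the calibration check.

source("analysis/_common.R")

co <- study_cohorts()
blood <- co$blood
filt <- probe_range_filter(blood$beta)
m <- beta_to_m(blood$beta)
dd <- discovery_design(blood)

res <- run_ewas(m[filt$retained, , drop = FALSE], dd$design,
                manifest = blood$manifest)
cat(sprintf("EWAS over %d probes, %d samples; lambda = %.3f\n",
            nrow(res), res$n[1], attr(res, "lambda")))

hits <- res[res$p_adj < 0.05, ]
cat(sprintf("FDR<0.05 discoveries: %d (%d truly causal)\n", nrow(hits),
            sum(hits$probe_id %in% names(blood$truth$causal))))
print(utils::head(res[c("probe_id", "gene", "coef", "p", "p_adj")], 10),
      digits = 3)

write_results(res, file.path(results_dir(), "discovery_ewas.tsv"))

# full-table fits (including low-variation probes) retained for
# candidate-probe replication, which re-applies its own FDR scope
res_all <- run_ewas(m, dd$design, manifest = blood$manifest)
write_results(res_all, file.path(results_dir(), "discovery_ewas_allprobes.tsv"))
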