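#!/usr/bin/env Rscript
# Stage 1: generate the three synthetic cohorts (discovery blood,
# 450K-restricted replication, paired-region brain) and write them out as
# plain-text tables for inspection. Everything downstream can rebuild the
# same cohorts from the seed, so these files are a data product, not a
# dependency.

source("analysis/_common.R")

co <- study_cohorts()
dir.create("scratch", showWarnings = FALSE)
write_cohort(co$blood, "scratch/cohort_discovery")
write_cohort(co$replication, "scratch/cohort_replication")
write_cohort(co$brain, "scratch/cohort_brain")

cat(sprintf("discovery:   %d probes x %d samples (%d cases / %d controls)\n",
            nrow(co$blood$beta), ncol(co$blood$beta),
            sum(co$blood$phenotypes$ptsd == 1),
            sum(co$blood$phenotypes$ptsd == 0)))
cat(sprintf("replication: %d probes on both platforms, %d samples\n",
            nrow(co$replication$beta), ncol(co$replication$beta)))
cat(sprintf("brain:       %d donors x 2 regions = %d samples\n",
            length(unique(co$brain$phenotypes$subject_id)),
            ncol(co$brain$beta)))
cat(sprintf("spiked: %d causal probes (plus correlated neighbors), %d smoking probes, %d meQTLs\n",
            co$config$n_causal_probes, co$config$n_smoking_probes,
            co$config$n_snps))
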