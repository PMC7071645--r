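#!/usr/bin/env Rscript
# Stage 7: probe-count-bias-corrected gene-set enrichment of the genes
# behind the top 500 discovery probes, against synthetic gene sets that
# include one set spiked with causal genes.

source("analysis/_common.R")

co <- study_cohorts()
blood <- co$blood

filt <- probe_range_filter(blood$beta)
dd <- discovery_design(blood)
disc_res <- run_ewas(beta_to_m(blood$beta)[filt$retained, , drop = FALSE],
                     dd$design, manifest = blood$manifest)

sets <- synthetic_gene_sets(blood$manifest, blood$truth, n_sets = 30,
                            seed = co$config$seed)
enr <- run_enrichment(disc_res, blood$manifest, sets,
                      k = min(500, nrow(disc_res)))
cat(sprintf("%d sets tested; %d with p_adj < 0.05; leader: %s (p = %.3g)\n",
            nrow(enr), sum(enr$p_adj < 0.05), enr$set[1], enr$p[1]))
print(utils::head(enr[c("set", "n_genes", "n_de", "p", "p_adj")], 6),
      digits = 3)

utils::write.csv(enr, file.path(results_dir(), "enrichment.csv"),
                 row.names = FALSE)
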