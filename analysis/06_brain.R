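#!/usr/bin/env Rscript
# Stage 6: paired brain analysis. The top 100 discovery loci are refit in
# the two-region brain cohort with a random subject intercept; estimated
# neuron fraction replaces the blood cell fractions; BH over the loci
# examined. Per-region follow-up fits check the joint-model leader.

source("analysis/_common.R")

co <- study_cohorts()
blood <- co$blood
brain <- co$brain

filt <- probe_range_filter(blood$beta)
dd <- discovery_design(blood)
disc_res <- run_ewas(beta_to_m(blood$beta)[filt$retained, , drop = FALSE],
                     dd$design, manifest = blood$manifest)

m_b <- beta_to_m(brain$beta)
ph <- brain$phenotypes
ph$neuron_fraction <- estimate_neuron_fraction(brain$beta,
                                               brain$cell_reference)[ph$sample_id]
cat(sprintf("estimated neuron fraction: r = %.3f vs truth\n",
            stats::cor(ph$neuron_fraction,
                       brain$truth$neuron_fraction[ph$subject_id])))
ph$region_vmpfc <- as.integer(ph$region == "vmPFC")
design_b <- build_design(ph, covariates = c("age", "sex", "smoking_status",
                                            "neuron_fraction", "region_vmpfc"))
subject <- ph$subject_id[match(rownames(design_b$X), ph$sample_id)]

top100 <- intersect(utils::head(disc_res$probe_id, 100), rownames(m_b))
res <- run_brain_ewas(m_b, top100, design_b, subject, manifest = brain$manifest)
cat(sprintf("brain refits of %d loci; %d with p_adj < 0.05; mean ICC = %.2f\n",
            nrow(res), sum(res$p_adj < 0.05), mean(res$icc)))
print(utils::head(res[c("probe_id", "gene", "coef", "p", "p_adj", "icc")], 5),
      digits = 3)

lead <- res$probe_id[1]
region <- ph$region[match(rownames(design_b$X), ph$sample_id)]
for (rg in c("dlPFC", "vmPFC")) {
  f <- per_region_fit(m_b[lead, rownames(design_b$X)], design_b$X, region, rg)
  cat(sprintf("leader %s in %s alone: coef = %.3f, p = %.3g\n",
              lead, rg, f$coef, f$p))
}

write_results(res, file.path(results_dir(), "brain_results.tsv"))
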