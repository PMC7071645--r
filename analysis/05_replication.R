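#!/usr/bin/env Rscript
# Stage 5: cross-cohort replication. The top 100 discovery loci are carried
# into the 450K replication cohort directly or via correlated proxy probes;
# the report combines the excess-significance binomial test, the
# direction-agreement sign test, effect-size correlations by replication-p
# strata, and BH over the loci actually examined.

source("analysis/_common.R")

co <- study_cohorts()
blood <- co$blood
repl <- co$replication

filt <- probe_range_filter(blood$beta)
dd <- discovery_design(blood)
disc_res <- run_ewas(beta_to_m(blood$beta)[filt$retained, , drop = FALSE],
                     dd$design, manifest = blood$manifest)

m_r <- beta_to_m(repl$beta)
cells_r <- estimate_fractions(repl$beta, repl$cell_reference)
phen_r <- repl$phenotypes
phen_r$smoking_score <- suppressWarnings(
  compute_smoking_score(m_r, repl$smoking_weights))[phen_r$sample_id]
design_r <- build_design(phen_r, covariates = c("age", "sex", "smoking_score"),
                         cell_fractions = cells_r$fractions)
repl_res <- run_ewas(m_r[intersect(filt$retained, rownames(m_r)), , drop = FALSE],
                     design_r, manifest = repl$manifest)

rep_out <- replicate_top_loci(disc_res, repl_res, blood$manifest, blood$beta,
                              k = 100)
cat(sprintf("loci examined: %d of top 100 (%d via proxy)\n",
            rep_out$n_examined, sum(rep_out$loci$is_proxy)))
cat(sprintf("nominally significant: %d (binomial p = %.3g)\n",
            rep_out$n_nominal, rep_out$excess_p))
cat(sprintf("direction agreement: %d/%d at replication p<0.10 (sign test p = %.3g)\n",
            rep_out$n_agree, rep_out$n_direction, rep_out$sign_p))
print(rep_out$correlations, digits = 3)

utils::write.csv(rep_out$loci, file.path(results_dir(), "replication_loci.csv"),
                 row.names = FALSE)
jsonlite::write_json(
  rep_out[c("n_examined", "n_nominal", "excess_p", "n_direction", "n_agree",
            "sign_p", "correlations")],
  file.path(results_dir(), "replication_report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
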