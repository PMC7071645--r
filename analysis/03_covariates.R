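#!/usr/bin/env Rscript
# Stage 3: molecular covariates. Cell-type fractions are estimated by
# constrained projection onto the cohort's reference profiles; the
# DNA-methylation smoking score is the weighted M-value sum over the score
# probes. Both are validated against the generator's ground truth before
# entering the design matrix.

source("analysis/_common.R")

co <- study_cohorts()
blood <- co$blood

cells <- estimate_fractions(blood$beta, blood$cell_reference)
frac_err <- mean(abs(cells$fractions -
                       blood$truth$cell_fractions[rownames(cells$fractions), ]))
cat(sprintf("cell fractions: mean absolute error vs truth = %.4f\n", frac_err))

m <- beta_to_m(blood$beta)
score <- compute_smoking_score(m, blood$smoking_weights)
phen <- blood$phenotypes
phen$smoking_score <- score[phen$sample_id]
chk <- validate_score(score, phen)
cat(sprintf("smoking score vs status: t-test p = %.3g (n = %d)\n",
            chk$status_p, chk$n_status))
cat(sprintf("smoking score vs cigarettes/day: r = %.3f, p = %.3g\n",
            chk$cigs_r, chk$cigs_p))

out <- data.frame(sample_id = rownames(cells$fractions), cells$fractions,
                  smoking_score = score[rownames(cells$fractions)],
                  check.names = FALSE)
utils::write.csv(out, file.path(results_dir(), "covariates.csv"),
                 row.names = FALSE)
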