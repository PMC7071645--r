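# Shared setup for the analysis drivers. Cohorts are rebuilt
# deterministically from the study configuration, so each driver is
# self-contained and any stage can be re-run in isolation.

suppressMessages(library(methewas))

STUDY_SEED <- 2026L

study_config <- function() sim_config(seed = STUDY_SEED)

study_cohorts <- function() {
  cfg <- study_config()
  blood <- simulate_blood_cohort(cfg)
  list(config = cfg,
       blood = blood,
       replication = simulate_replication_cohort(cfg, blood,
                                                 effect_attenuation = 0.8),
       brain = simulate_brain_cohort(cfg))
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}

# Discovery design shared by stages 04, 05 and 08.
discovery_design <- function(blood) {
  cells <- estimate_fractions(blood$beta, blood$cell_reference)
  phen <- blood$phenotypes
  phen$smoking_score <- compute_smoking_score(beta_to_m(blood$beta),
                                              blood$smoking_weights)[phen$sample_id]
  list(design = build_design(phen, covariates = c("age", "sex", "smoking_score"),
                             cell_fractions = cells$fractions),
       phenotypes = phen, cells = cells)
}
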