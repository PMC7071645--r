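# End-to-end orchestration: simulate -> preprocess -> covariates -> EWAS ->
# replication -> brain -> enrichment -> sensitivity, from one configuration.

#' Build synthetic gene sets from a manifest
#'
#' Random gene sets drawn from the manifest's gene universe, plus one
#' "spiked" set enriched for the genes that carry true causal probes (when
#' a truth map is supplied), for exercising the enrichment stage.
#'
#' @param manifest Probe manifest.
#' @param truth Optional truth list with a `causal` named vector.
#' @param n_sets Number of random sets (default 20).
#' @param set_size Genes per set (default 25).
#' @param seed RNG seed.
#' @return Named list of gene symbol vectors.
#' @export
synthetic_gene_sets <- function(manifest, truth = NULL, n_sets = 20,
                                set_size = 25, seed = 1) {
  genes <- unique(toupper(unlist(strsplit(manifest$gene, ";", fixed = TRUE))))
  genes <- genes[nzchar(genes)]
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) sample(genes, min(set_size, length(genes))))
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    if (!is.null(truth$causal)) {
      causal_genes <- unique(toupper(unlist(strsplit(
        manifest$gene[manifest$probe_id %in% names(truth$causal)], ";",
        fixed = TRUE))))
      causal_genes <- causal_genes[nzchar(causal_genes)]
      filler <- sample(setdiff(genes, causal_genes),
                       max(0, set_size - length(causal_genes)))
      sets$SPIKED <- unique(c(causal_genes, filler))
    }
    sets
  })
}

#' Default pipeline configuration
#'
#' Stage parameters mirroring the emulated study: minimum beta range 0.10,
#' proxy window 5000 bp, replication over the top 100 loci, enrichment over
#' the top 500, nominal alpha 0.05 and direction threshold 0.10.
#'
#' @param sim A [sim_config()] (default `sim_config()`).
#' @return Named list of pipeline parameters.
#' @export
pipeline_config <- function(sim = sim_config()) {
  list(sim = sim, min_range = 0.10, top_k_replication = 100,
       top_k_enrichment = 500, alpha = 0.05, direction_threshold = 0.10,
       proxy_window = 5000, effect_attenuation = 1,
       n_sensitivity_probes = 5)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; entries under `sim`
#' override [sim_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return Pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  sim <- if (is.null(sim_args)) sim_config() else do.call(sim_config, sim_args)
  cfg <- pipeline_config(sim)
  for (nm in setdiff(names(raw), "sim")) cfg[[nm]] <- raw[[nm]]
  cfg
}

#' Run the full pipeline on simulated cohorts
#'
#' Executes every stage in order and returns a summary: filter counts,
#' genomic inflation, the top discovery table, the replication report, the
#' brain table, the enrichment table, and the sensitivity report. Identical
#' configuration and seed give an identical summary.
#'
#' @param config A pipeline configuration ([pipeline_config()]).
#' @param gene_sets Optional named list of gene sets; defaults to
#'   [synthetic_gene_sets()] built from the simulated manifest.
#' @param verbose Emit stage messages (default TRUE).
#' @return List of stage outputs (class `ewas_pipeline_summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), gene_sets = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) msg_log(...)
  sim <- config$sim

  say("simulating cohorts (seed %d)", sim$seed)
  blood <- simulate_blood_cohort(sim)
  repl <- simulate_replication_cohort(sim, blood,
                                      effect_attenuation = config$effect_attenuation)
  brain <- simulate_brain_cohort(sim)

  say("probe range filter (min range %.2f)", config$min_range)
  filt <- probe_range_filter(blood$beta, min_range = config$min_range)
  m_blood <- beta_to_m(blood$beta)
  m_analysis <- m_blood[filt$retained, , drop = FALSE]

  say("cell composition and smoking score")
  cells <- estimate_fractions(blood$beta, blood$cell_reference)
  score <- compute_smoking_score(m_blood, blood$smoking_weights)
  phen <- blood$phenotypes
  phen$smoking_score <- score[phen$sample_id]
  score_check <- validate_score(score, phen)

  say("discovery EWAS over %d probes", nrow(m_analysis))
  design <- build_design(phen, covariates = c("age", "sex", "smoking_score"),
                         cell_fractions = cells$fractions)
  disc <- run_ewas(m_analysis, design, manifest = blood$manifest)

  say("replication in the 450K cohort")
  m_repl <- beta_to_m(repl$beta)
  repl_filt <- intersect(filt$retained, rownames(m_repl))
  cells_r <- estimate_fractions(repl$beta, repl$cell_reference)
  phen_r <- repl$phenotypes
  phen_r$smoking_score <- compute_smoking_score(m_repl, repl$smoking_weights)[phen_r$sample_id]
  design_r <- build_design(phen_r, covariates = c("age", "sex", "smoking_score"),
                           cell_fractions = cells_r$fractions)
  repl_res <- run_ewas(m_repl[repl_filt, , drop = FALSE], design_r,
                       manifest = repl$manifest)
  repl_report <- replicate_top_loci(
    disc, repl_res, blood$manifest, blood$beta,
    k = min(config$top_k_replication, nrow(disc)),
    alpha = config$alpha,
    direction_threshold = config$direction_threshold,
    proxy_window = config$proxy_window)

  say("paired brain analysis")
  m_brain <- beta_to_m(brain$beta)
  phen_b <- brain$phenotypes
  phen_b$neuron_fraction <- estimate_neuron_fraction(brain$beta,
                                                     brain$cell_reference)[phen_b$sample_id]
  phen_b$region_vmpfc <- as.integer(phen_b$region == "vmPFC")
  design_b <- build_design(phen_b,
                           covariates = c("age", "sex", "smoking_status",
                                          "neuron_fraction", "region_vmpfc"))
  top_brain <- utils::head(disc$probe_id, min(config$top_k_replication, nrow(disc)))
  top_brain <- intersect(top_brain, rownames(m_brain))
  brain_res <- run_brain_ewas(m_brain, top_brain, design_b,
                              subject = phen_b$subject_id[match(rownames(design_b$X),
                                                                phen_b$sample_id)],
                              manifest = brain$manifest)

  say("gene-set enrichment over the top %d probes", config$top_k_enrichment)
  if (is.null(gene_sets)) {
    gene_sets <- synthetic_gene_sets(blood$manifest, blood$truth,
                                     seed = sim$seed)
  }
  enrich <- run_enrichment(disc, blood$manifest, gene_sets,
                           k = min(config$top_k_enrichment, nrow(disc)))

  say("sensitivity refits for the top %d probes", config$n_sensitivity_probes)
  sens <- sensitivity_report(
    m_analysis, utils::head(disc$probe_id, config$n_sensitivity_probes),
    design$X, phen, manifest = blood$manifest)

  structure(list(
    filter = filt$report[c("n_input", "n_excluded_low_range",
                           "n_excluded_all_missing", "n_retained")],
    lambda = attr(disc, "lambda"),
    score_check = score_check,
    discovery_top = utils::head(disc, 10L),
    discovery = disc,
    replication_report = repl_report,
    brain = brain_res,
    enrichment = enrich,
    sensitivity = sens,
    truth = blood$truth,
    config = config
  ), class = "ewas_pipeline_summary")
}

#' Write a pipeline summary as JSON
#' @param summary An `ewas_pipeline_summary`.
#' @param path Output path.
#' @export
write_pipeline_summary <- function(summary, path) {
  out <- list(
    filter = summary$filter,
    lambda = summary$lambda,
    discovery_top = summary$discovery_top,
    replication = summary$replication_report[c("n_examined", "n_nominal",
                                               "excess_p", "n_direction",
                                               "n_agree", "sign_p")],
    correlations = summary$replication_report$correlations,
    brain_top = utils::head(summary$brain, 5L),
    enrichment_top = utils::head(summary$enrichment, 5L)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
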