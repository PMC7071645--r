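# Synthetic cohort generators.
#
# Three generators emulate the study design end-to-end so that every
# pipeline stage is testable with known ground truth: a discovery blood
# cohort, an independent replication cohort restricted to 450K-platform
# probes, and a paired two-region brain cohort with subject-level random
# intercepts. Data are generated on the M-value scale, where the analysis
# models are linear and ground-truth effects are exact, then inverse-logit
# transformed to beta values.

#' Construct and validate a simulation configuration
#'
#' Defaults mirror the emulated study design: 378 cases and 135 controls in
#' blood, 42 case and 30 control donors with two prefrontal-cortex regions
#' each, 39 smoking-score probes, six white-blood-cell types, a 5% minimum
#' minor allele frequency for simulated variants, and spiked case effects of
#' 0.3 on the M scale (the midpoint of the 0.11-0.53 magnitude range typical
#' of top blood findings). `low_var_fraction` controls the share of probes
#' built to fail the 0.10 beta-range filter.
#'
#' @param n_cases,n_controls Blood cohort group sizes.
#' @param n_probes Number of probes.
#' @param n_cell_types Number of blood cell types.
#' @param dirichlet_concentration Dirichlet concentration per cell type
#'   (length `n_cell_types`; default is a granulocyte-dominated profile).
#' @param n_causal_probes Number of probes with a true case/control effect.
#' @param causal_effect_m Case effect per causal probe, M scale.
#' @param n_smoking_probes Probes with smoking effects (includes the 39
#'   score probes).
#' @param smoking_effect_m Smoking effect, M scale (negative:
#'   hypomethylation in smokers).
#' @param smoker_fraction_cases,smoker_fraction_controls Smoking prevalence
#'   by group (confounded by design, as in trauma-exposed cohorts).
#' @param n_pcs Ancestry principal components.
#' @param pc_effect_sd Standard deviation of per-probe PC loadings.
#' @param age_range Age range, years.
#' @param residual_sd_m Residual standard deviation, M scale.
#' @param n_snps Number of simulated nearby variants (meQTLs).
#' @param meqtl_effect_m Per-allele dosage effect, M scale.
#' @param brain_icc Within-subject correlation of the two brain regions.
#' @param platform_450k_fraction Fraction of probes flagged as present on
#'   both platforms.
#' @param low_var_fraction Fraction of probes generated as low-variation.
#' @param n_brain_cases,n_brain_controls Brain cohort donor counts.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 378, n_controls = 135, n_probes = 4000,
                       n_cell_types = 6,
                       dirichlet_concentration = NULL,
                       n_causal_probes = 50, causal_effect_m = 0.3,
                       n_smoking_probes = 39, smoking_effect_m = -1,
                       smoker_fraction_cases = 0.5,
                       smoker_fraction_controls = 0.3,
                       n_pcs = 3, pc_effect_sd = 0.1,
                       age_range = c(20, 65), residual_sd_m = 1,
                       n_snps = 20, meqtl_effect_m = 0.4,
                       brain_icc = 0.6, platform_450k_fraction = 0.54,
                       low_var_fraction = 0.3,
                       n_brain_cases = 42, n_brain_controls = 30,
                       seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$dirichlet_concentration)) {
    base <- c(20, 6, 4, 3, 2, 2, 1.5, 1.5)
    cfg$dirichlet_concentration <- base[seq_len(n_cell_types)]
  }
  for (nm in c("n_cases", "n_controls", "n_probes", "n_cell_types",
               "n_causal_probes", "n_smoking_probes", "n_pcs", "n_snps",
               "n_brain_cases", "n_brain_controls")) {
    assert_count(cfg[[nm]], nm)
  }
  for (nm in c("smoker_fraction_cases", "smoker_fraction_controls",
               "platform_450k_fraction", "low_var_fraction")) {
    assert_prob(cfg[[nm]], nm)
  }
  nums <- unlist(cfg[c("causal_effect_m", "smoking_effect_m", "pc_effect_sd",
                       "residual_sd_m", "meqtl_effect_m", "brain_icc",
                       "age_range", "dirichlet_concentration", "seed")])
  if (any(!is.finite(nums))) stop("configuration parameters must be finite", call. = FALSE)
  if (cfg$residual_sd_m <= 0) stop("residual_sd_m must be positive", call. = FALSE)
  if (cfg$brain_icc < 0 || cfg$brain_icc >= 1) stop("brain_icc must lie in [0, 1)", call. = FALSE)
  if (any(cfg$dirichlet_concentration <= 0)) {
    stop("dirichlet concentrations must be positive", call. = FALSE)
  }
  if (length(cfg$dirichlet_concentration) != cfg$n_cell_types) {
    stop("dirichlet_concentration must have one entry per cell type", call. = FALSE)
  }
  n_special <- cfg$n_causal_probes + cfg$n_smoking_probes + cfg$n_snps
  n_informative <- cfg$n_probes - round(cfg$low_var_fraction * cfg$n_probes)
  if (2 * cfg$n_causal_probes + cfg$n_smoking_probes + cfg$n_snps > n_informative) {
    stop("too few probes for the requested causal/smoking/meQTL assignments",
         call. = FALSE)
  }
  if (n_special > cfg$n_probes) stop("n_causal_probes (etc.) exceed n_probes", call. = FALSE)
  structure(cfg, class = "sim_config")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

# Probe-level structure shared by all cohorts derived from one config:
# baselines, low-variation class, causal/smoking/meQTL assignments,
# cell-type deviations, covariate loadings, manifest. Deterministic in the
# config seed, so the blood and brain generators agree on probe identity.
probe_structure <- function(config) {
  with_seed(config$seed, {
    np <- config$n_probes
    probe_ids <- sprintf("cg%07d", seq_len(np))
    n_low <- round(config$low_var_fraction * np)
    low <- rep(FALSE, np)
    if (n_low > 0) low[sample.int(np, n_low)] <- TRUE
    beta0 <- numeric(np)
    # low-variation probes sit near the boundaries (fully methylated or
    # unmethylated); intermediate probes are drawn across a wide range
    hi_tail <- stats::runif(np) < 0.5
    beta0[low & hi_tail] <- stats::runif(sum(low & hi_tail), 0.955, 0.985)
    beta0[low & !hi_tail] <- stats::runif(sum(low & !hi_tail), 0.015, 0.045)
    beta0[!low] <- stats::runif(sum(!low), 0.2, 0.8)
    m0 <- beta_to_m(beta0)

    informative <- which(!low)
    pick <- function(n, from) {
      taken <- sample(from, n)
      list(taken = taken, rest = setdiff(from, taken))
    }
    pool <- informative
    cz <- pick(config$n_causal_probes, pool); causal <- cz$taken; pool <- cz$rest
    # each causal probe gets a designated neighbor probe for the proxy logic
    nb <- pick(config$n_causal_probes, pool); neighbor <- nb$taken; pool <- nb$rest
    sm <- pick(config$n_smoking_probes, pool); smoking <- sm$taken; pool <- sm$rest
    mq <- pick(config$n_snps, pool); meqtl_target <- mq$taken; pool <- mq$rest

    causal_eff <- rep(config$causal_effect_m, length(causal))
    smoking_eff <- config$smoking_effect_m * stats::runif(length(smoking), 0.5, 1.5)
    neighbor_rho <- 0.75  # neighbors inherit this share of the causal signal

    # cell-informative probes: strong cell-type contrasts on a subset, used
    # as the deconvolution reference
    n_ref <- min(max(120L, np %/% 10L), length(pool))
    ref_probes <- sort(sample(pool, n_ref))
    K <- config$n_cell_types
    delta <- matrix(0, np, K)
    delta[ref_probes, ] <- stats::rnorm(n_ref * K, sd = 1.5)
    cell_names <- c("Gran", "CD4T", "CD8T", "Mono", "Bcell", "NK",
                    paste0("CT", seq_len(max(0, K - 6))))[seq_len(K)]

    # small per-probe covariate loadings (null probes still move with
    # age/sex/ancestry, as real methylation does)
    age_load <- stats::rnorm(np, sd = 0.005)
    sex_load <- stats::rnorm(np, sd = 0.1)
    pc_load <- matrix(stats::rnorm(np * config$n_pcs, sd = config$pc_effect_sd),
                      np, config$n_pcs)
    age_load[low] <- 0; sex_load[low] <- 0; pc_load[low, ] <- 0

    # manifest: probes laid along chromosomes with irregular gaps; each
    # causal probe's neighbor is placed 1-2 kb away on the same chromosome
    chr <- sort(sample(1:22, np, replace = TRUE))
    pos <- unlist(tapply(chr, chr, function(x) {
      cumsum(round(stats::runif(length(x), 500, 20000))) + 10000L
    }, simplify = FALSE), use.names = FALSE)
    chr_lab <- paste0("chr", chr)
    chr_lab[neighbor] <- chr_lab[causal]
    pos[neighbor] <- pos[causal] + round(stats::runif(length(causal), 800, 2000))

    on_450k <- stats::runif(np) < config$platform_450k_fraction
    on_450k[neighbor] <- TRUE  # guarantee a cross-platform proxy exists

    # genes in blocks of 1-8 consecutive probes; ~15% intergenic
    gene <- character(np)
    i <- 1L; gidx <- 0L
    while (i <= np) {
      size <- sample(1:8, 1L)
      block <- i:min(np, i + size - 1L)
      gidx <- gidx + 1L
      gene[block] <- sprintf("GENE%04d", gidx)
      i <- i + size
    }
    gene[stats::runif(np) < 0.15] <- ""

    snp_ids <- if (config$n_snps > 0) sprintf("rs%06d", seq_len(config$n_snps)) else character()
    snps <- character(np)
    snps[meqtl_target] <- snp_ids
    maf <- stats::runif(config$n_snps, 0.05, 0.5)

    manifest <- data.frame(
      probe_id = probe_ids, chr = chr_lab, pos = pos, gene = gene,
      on_450k = on_450k, on_epic = TRUE, snps = snps,
      stringsAsFactors = FALSE)

    list(probe_ids = probe_ids, m0 = m0, low = low,
         causal = causal, causal_eff = causal_eff,
         neighbor = neighbor, neighbor_rho = neighbor_rho,
         smoking = smoking, smoking_eff = smoking_eff,
         meqtl_target = meqtl_target, snp_ids = snp_ids, maf = maf,
         delta = delta, ref_probes = ref_probes, cell_names = cell_names,
         age_load = age_load, sex_load = sex_load, pc_load = pc_load,
         manifest = manifest)
  })
}

# Shared sample-level generation for blood-like cohorts. Returns the bundle
# pieces for `n_cases`/`n_controls` new samples against a probe structure,
# with all true effects scaled by `effect_scale`.
generate_blood_samples <- function(config, ps, n_cases, n_controls,
                                   effect_scale, id_prefix) {
  n <- n_cases + n_controls
  np <- config$n_probes
  sample_ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  ptsd <- c(rep(1L, n_cases), rep(0L, n_controls))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1L, 0.9)
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
  smoker <- stats::rbinom(n, 1L, ifelse(ptsd == 1,
                                        config$smoker_fraction_cases,
                                        config$smoker_fraction_controls))
  cigs <- smoker * stats::rgamma(n, shape = 4, scale = 4)
  fracs <- rdirichlet(n, config$dirichlet_concentration)
  colnames(fracs) <- ps$cell_names
  rownames(fracs) <- sample_ids
  dosage <- if (config$n_snps > 0) {
    d <- vapply(ps$maf, function(f) stats::rbinom(n, 2L, f), numeric(n))
    colnames(d) <- ps$snp_ids
    d
  } else matrix(0, n, 0)

  causal_eff <- ps$causal_eff * effect_scale
  smoking_eff <- ps$smoking_eff  # smoking biology is not attenuated
  meqtl_eff <- config$meqtl_effect_m * effect_scale

  # M = baseline + cell mixture + covariate terms + spiked effects + noise
  m <- matrix(ps$m0, np, n) +
    ps$delta %*% t(fracs) +
    outer(ps$age_load, age - mean(config$age_range)) +
    outer(ps$sex_load, sex - 0.5) +
    ps$pc_load %*% t(pcs)
  m[ps$causal, ] <- m[ps$causal, ] + causal_eff %o% ptsd
  m[ps$smoking, ] <- m[ps$smoking, ] + smoking_eff %o% smoker
  if (config$n_snps > 0) {
    m[ps$meqtl_target, ] <- m[ps$meqtl_target, ] + meqtl_eff * t(dosage)
  }
  res_sd <- ifelse(ps$low, 0.25 * config$residual_sd_m, config$residual_sd_m)
  noise <- matrix(stats::rnorm(np * n), np, n) * res_sd
  m <- m + noise
  # neighbors mix in a share of their causal probe's full signal (including
  # the case effect), creating the correlated proxies the replication
  # pipeline relies on
  m[ps$neighbor, ] <- ps$neighbor_rho * (m[ps$causal, ] - ps$m0[ps$causal]) +
    matrix(ps$m0[ps$neighbor], length(ps$neighbor), n) +
    sqrt(1 - ps$neighbor_rho^2) * config$residual_sd_m *
      matrix(stats::rnorm(length(ps$neighbor) * n), length(ps$neighbor), n)
  dimnames(m) <- list(ps$probe_ids, sample_ids)

  beta <- m_to_beta(m)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)

  phen <- data.frame(
    sample_id = sample_ids, subject_id = sample_ids, ptsd = ptsd,
    age = age, sex = sex, stringsAsFactors = FALSE)
  for (j in seq_len(config$n_pcs)) phen[[paste0("pc", j)]] <- pcs[, j]
  phen$smoking_status <- smoker
  phen$cigarettes_per_day <- cigs
  phen$depression <- stats::rbinom(n, 1L, ifelse(ptsd == 1, 0.5, 0.2))
  phen$ssri <- stats::rbinom(n, 1L, ifelse(phen$depression == 1, 0.4, 0.1))
  phen$alcohol <- stats::rbinom(n, 1L, ifelse(ptsd == 1, 0.35, 0.2))
  phen$region <- "blood"
  for (j in seq_along(ps$snp_ids)) {
    phen[[paste0("snp_", ps$snp_ids[j])]] <- dosage[, j]
  }

  truth <- list(
    causal = stats::setNames(c(causal_eff, ps$neighbor_rho * causal_eff),
                             ps$probe_ids[c(ps$causal, ps$neighbor)]),
    smoking = stats::setNames(smoking_eff, ps$probe_ids[ps$smoking]),
    cell_fractions = fracs,
    meqtl = stats::setNames(ps$probe_ids[ps$meqtl_target], ps$snp_ids))

  list(beta = beta, phenotypes = phen, truth = truth)
}

cell_reference_from <- function(ps) {
  ref <- m_to_beta(ps$m0[ps$ref_probes] + ps$delta[ps$ref_probes, , drop = FALSE])
  dimnames(ref) <- list(ps$probe_ids[ps$ref_probes], ps$cell_names)
  ref
}

#' Simulate the discovery blood cohort
#'
#' Generates a case/control whole-blood cohort with cell-composition
#' structure, ancestry/age/sex covariate effects, smoking-driven
#' hypomethylation at designated score probes, spiked case effects at
#' causal probes (each with a correlated neighbor so cross-platform proxies
#' exist), and meQTL allele effects. All signals are added on the M scale
#' and inverse-logit transformed to beta.
#'
#' @param config A [sim_config()].
#' @return A `CohortBundle` list: `beta` (probe x sample matrix),
#'   `manifest`, `phenotypes`, `truth` (spiked effects, true cell
#'   fractions, meQTL targets), `cell_reference` (probe x cell-type beta
#'   matrix), `smoking_weights` (named vector over the score probes), and
#'   `config`.
#' @export
simulate_blood_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ps <- probe_structure(config)
  out <- with_seed(config$seed + 11L, {
    generate_blood_samples(config, ps, config$n_cases, config$n_controls,
                           effect_scale = 1, id_prefix = "D")
  })
  n_score <- min(39L, config$n_smoking_probes)
  weights <- stats::setNames(ps$smoking_eff[seq_len(n_score)],
                             ps$probe_ids[ps$smoking[seq_len(n_score)]])
  list(beta = out$beta, manifest = ps$manifest, phenotypes = out$phenotypes,
       truth = out$truth, cell_reference = cell_reference_from(ps),
       smoking_weights = weights, config = config)
}

#' Simulate the 450K replication cohort
#'
#' Independent samples generated against the discovery cohort's probe
#' structure, restricted to probes flagged on the 450K platform, with all
#' true case effects multiplied by `effect_attenuation` (cross-cohort
#' effect shrinkage).
#'
#' @param config The [sim_config()] used for the discovery cohort.
#' @param discovery The discovery `CohortBundle` (supplies the platform
#'   flags; a bundle without them is an error).
#' @param effect_attenuation Nonnegative effect scale (0 = pure null).
#' @return A `CohortBundle` with the 450K-only manifest.
#' @export
simulate_replication_cohort <- function(config, discovery,
                                        effect_attenuation = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(discovery$manifest$on_450k)) {
    stop("discovery bundle lacks platform flags", call. = FALSE)
  }
  if (!is.numeric(effect_attenuation) || effect_attenuation < 0) {
    stop("effect_attenuation must be >= 0", call. = FALSE)
  }
  ps <- probe_structure(config)
  out <- with_seed(config$seed + 23L, {
    generate_blood_samples(config, ps, config$n_cases, config$n_controls,
                           effect_scale = effect_attenuation,
                           id_prefix = "R")
  })
  keep <- discovery$manifest$probe_id[discovery$manifest$on_450k]
  out$truth$causal <- out$truth$causal[names(out$truth$causal) %in% keep]
  out$truth$smoking <- out$truth$smoking[names(out$truth$smoking) %in% keep]
  list(beta = out$beta[keep, , drop = FALSE],
       manifest = discovery$manifest[discovery$manifest$on_450k, , drop = FALSE],
       phenotypes = out$phenotypes, truth = out$truth,
       cell_reference = cell_reference_from(ps),
       smoking_weights = discovery$smoking_weights, config = config)
}

#' Simulate the paired brain cohort
#'
#' Each donor contributes a dorsolateral (dlPFC) and a ventromedial (vmPFC)
#' prefrontal-cortex sample. Probe M-values share a subject-level random
#' intercept whose variance is `brain_icc` of the total residual variance,
#' so the within-subject correlation of null probes equals `brain_icc`.
#' Methylation mixes a neuron and a glia profile according to each donor's
#' neuron fraction; the two-type reference is returned for deconvolution.
#'
#' @param config A [sim_config()].
#' @return A `CohortBundle`; `phenotypes` has two rows per subject with
#'   `region` and `neuron_fraction` columns, and `cell_reference` has
#'   `neuron` and `glia` columns.
#' @export
simulate_brain_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ps <- probe_structure(config)
  with_seed(config$seed + 37L, {
    ns <- config$n_brain_cases + config$n_brain_controls
    np <- config$n_probes
    subj_ids <- sprintf("B%03d", seq_len(ns))
    ptsd <- c(rep(1L, config$n_brain_cases), rep(0L, config$n_brain_controls))
    age <- stats::runif(ns, config$age_range[1], config$age_range[2])
    sex <- stats::rbinom(ns, 1L, 0.85)
    pcs <- matrix(stats::rnorm(ns * config$n_pcs), ns, config$n_pcs)
    smoker <- stats::rbinom(ns, 1L, ifelse(ptsd == 1,
                                           config$smoker_fraction_cases,
                                           config$smoker_fraction_controls))
    neuron <- stats::rbeta(ns, 8, 12)

    regions <- c("dlPFC", "vmPFC")
    sample_ids <- as.vector(t(outer(subj_ids, regions, paste, sep = "_")))
    subj_of <- rep(seq_len(ns), each = 2L)
    region_of <- rep(regions, ns)

    # two-type (neuron/glia) cell deviations reuse the first two reference
    # contrast columns, widened: neuron vs glia methylation differences are
    # among the largest cell-type contrasts on the array
    delta2 <- 1.8 * ps$delta[, 1:2, drop = FALSE]
    colnames(delta2) <- c("neuron", "glia")
    frac2 <- cbind(neuron = neuron, glia = 1 - neuron)

    sd_tot <- config$residual_sd_m
    sd_b <- sqrt(config$brain_icc) * sd_tot
    sd_e <- sqrt(1 - config$brain_icc) * sd_tot
    b_subj <- matrix(stats::rnorm(np * ns, sd = sd_b), np, ns)
    region_shift <- stats::rnorm(np, sd = 0.1)
    region_shift[ps$low] <- 0

    n_obs <- 2L * ns
    m <- matrix(ps$m0, np, n_obs) +
      delta2 %*% t(frac2[subj_of, , drop = FALSE]) +
      outer(ps$age_load, age[subj_of] - mean(config$age_range)) +
      outer(ps$sex_load, sex[subj_of] - 0.5) +
      ps$pc_load %*% t(pcs[subj_of, , drop = FALSE]) +
      b_subj[, subj_of] +
      outer(region_shift, as.numeric(region_of == "vmPFC"))
    m[ps$causal, ] <- m[ps$causal, ] + ps$causal_eff %o% ptsd[subj_of]
    res_sd <- ifelse(ps$low, 0.25 * sd_e, sd_e)
    m <- m + matrix(stats::rnorm(np * n_obs), np, n_obs) * res_sd
    dimnames(m) <- list(ps$probe_ids, sample_ids)
    beta <- pmin(pmax(m_to_beta(m), 1e-6), 1 - 1e-6)

    phen <- data.frame(
      sample_id = sample_ids, subject_id = subj_ids[subj_of],
      ptsd = ptsd[subj_of], age = age[subj_of], sex = sex[subj_of],
      stringsAsFactors = FALSE)
    for (j in seq_len(config$n_pcs)) phen[[paste0("pc", j)]] <- pcs[subj_of, j]
    phen$smoking_status <- smoker[subj_of]
    phen$region <- region_of
    phen$neuron_fraction_true <- neuron[subj_of]

    ref2 <- m_to_beta(ps$m0[ps$ref_probes] + delta2[ps$ref_probes, , drop = FALSE])
    dimnames(ref2) <- list(ps$probe_ids[ps$ref_probes], c("neuron", "glia"))

    truth <- list(
      causal = stats::setNames(ps$causal_eff, ps$probe_ids[ps$causal]),
      neuron_fraction = stats::setNames(neuron, subj_ids),
      icc = config$brain_icc)

    list(beta = beta, manifest = ps$manifest, phenotypes = phen,
         truth = truth, cell_reference = ref2, config = config)
  })
}

#' Write a simulated cohort bundle to plain-text files
#'
#' Emits the beta matrix (TSV), manifest, phenotypes, truth tables, and
#' cell reference (CSV) under a directory.
#'
#' @param bundle A `CohortBundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(bundle$beta, file.path(dir, "beta.tsv"))
  utils::write.csv(bundle$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(probe_id = names(bundle$truth$causal),
               effect_m = unname(bundle$truth$causal)),
    file.path(dir, "truth_causal.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(probe_id = rownames(bundle$cell_reference),
               bundle$cell_reference, check.names = FALSE),
    file.path(dir, "cell_reference.csv"), row.names = FALSE)
  if (!is.null(bundle$smoking_weights)) {
    utils::write.csv(
      data.frame(probe_id = names(bundle$smoking_weights),
                 weight = unname(bundle$smoking_weights)),
      file.path(dir, "smoking_weights.csv"), row.names = FALSE)
  }
  invisible(dir)
}
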