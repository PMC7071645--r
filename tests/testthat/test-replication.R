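test_that("exact binomial tails equal brute-force pmf summation", {
  for (n in c(1, 5, 14, 20)) {
    for (k in 0:n) {
      expect_equal(excess_significance_test(k, n, 0.05),
                   if (k == 0) 1 else binom_tail_oracle(k, n, 0.05),
                   tolerance = 1e-12)
      two_sided <- min(1, 2 * min(sum(dbinom(0:k, n, 0.5)),
                                  sum(dbinom(k:n, n, 0.5))))
      expect_equal(sign_agreement_test(k, n), two_sided, tolerance = 1e-12)
    }
  }
  # boundary and symmetry identities
  expect_equal(excess_significance_test(60, 60, 0.05), 0.05^60)
  expect_equal(sign_agreement_test(7, 14), 1.0)
  expect_equal(sign_agreement_test(0, 14), sign_agreement_test(14, 14))
  expect_error(excess_significance_test(5, 3), "exceed")
  expect_error(excess_significance_test(1, 3, alpha = 1.2), "alpha")
})

test_that("sign test agrees with the standard exact binomial test", {
  for (n in c(6, 14)) {
    for (k in 0:n) {
      expect_equal(sign_agreement_test(k, n),
                   stats::binom.test(k, n, 0.5)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("proxy selection prefers itself, then the strongest correlate", {
  man <- data.frame(
    probe_id = c("peak", "near_hi", "near_lo", "far", "both"),
    chr = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    pos = c(10000, 12000, 13000, 40000, 10500),
    gene = "G", on_450k = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    on_epic = TRUE, snps = "", stringsAsFactors = FALSE)
  set.seed(31)
  n <- 60
  base <- rnorm(n)
  beta <- rbind(
    peak = pnorm(base),
    near_hi = pnorm(0.9 * base + sqrt(1 - 0.81) * rnorm(n)),
    near_lo = pnorm(0.6 * base + 0.8 * rnorm(n)),
    far = pnorm(0.95 * base + 0.3 * rnorm(n)),
    both = pnorm(rnorm(n)))
  colnames(beta) <- paste0("s", 1:n)

  pr <- find_proxy("peak", man, beta)
  expect_equal(pr$proxy, "near_hi")
  expect_equal(pr$distance, 2000)
  expect_gt(pr$r, 0.6)

  # a peak on both platforms is its own proxy
  pr2 <- find_proxy("both", man, beta)
  expect_equal(pr2$proxy, "both")
  expect_equal(pr2$distance, 0)

  # no eligible candidate within the window
  man_far <- man
  man_far$pos[2:3] <- c(99000, 98000)
  pr3 <- find_proxy("peak", man_far, beta)
  expect_true(is.na(pr3$proxy))
  expect_error(find_proxy("nope", man, beta), "absent")
})

test_that("effect correlations report exact trivial cases and strata", {
  x <- c(0.3, -0.2, 0.5, 0.1, -0.4)
  out <- effect_correlation(x, x, rep(0.01, 5))
  expect_equal(out$r[out$stratum == "all"], 1.0)
  out_neg <- effect_correlation(x, -x, rep(0.01, 5))
  expect_equal(out_neg$r[out_neg$stratum == "all"], -1.0)
  # undersized stratum is NA, not an error
  out_small <- effect_correlation(x, x, c(0.01, 0.5, 0.5, 0.5, 0.5))
  expect_true(is.na(out_small$r[out_small$stratum == "p<0.05"]))
  expect_equal(out_small$n[out_small$stratum == "p<0.05"], 1)
})

test_that("replication of a same-effect re-simulation detects agreement", {
  cfg <- tiny_config(n_probes = 900, n_cases = 250, n_controls = 150,
                     n_causal_probes = 30, causal_effect_m = 0.6, seed = 33)
  disc_b <- simulate_blood_cohort(cfg)
  repl_b <- simulate_replication_cohort(cfg, disc_b, effect_attenuation = 1)
  m_d <- beta_to_m(disc_b$beta)
  m_r <- beta_to_m(repl_b$beta)
  d_d <- build_design(disc_b$phenotypes, covariates = c("age", "sex"))
  d_r <- build_design(repl_b$phenotypes, covariates = c("age", "sex"))
  keep <- probe_range_filter(disc_b$beta)$retained
  disc <- run_ewas(m_d[keep, ], d_d)
  repl <- run_ewas(m_r[intersect(keep, rownames(m_r)), ], d_r)
  rep_out <- replicate_top_loci(disc, repl, disc_b$manifest, disc_b$beta,
                                k = 50)
  expect_lte(rep_out$n_examined, 50)
  expect_gte(rep_out$n_examined, 10)
  expect_lt(rep_out$sign_p, 0.05)
  expect_lt(rep_out$excess_p, 0.05)
  # internal consistency: nested strata, counts coherent
  expect_lte(rep_out$n_nominal, rep_out$n_examined)
  expect_lte(rep_out$n_agree, rep_out$n_direction)
  corr <- rep_out$correlations
  expect_lte(corr$n[corr$stratum == "p<0.05"], corr$n[corr$stratum == "p<0.1"])
  expect_lte(corr$n[corr$stratum == "p<0.1"], corr$n[corr$stratum == "all"])
  expect_equal(sort(rep_out$loci$p_adj),
               sort(bh_oracle(rep_out$loci$repl_p)), tolerance = 1e-12)
})

test_that("pure-null replication yields the expected nominal rate", {
  cfg <- tiny_config(n_probes = 700, n_cases = 150, n_controls = 150,
                     n_causal_probes = 20, seed = 34)
  disc_b <- simulate_blood_cohort(cfg)
  repl_b <- simulate_replication_cohort(cfg, disc_b, effect_attenuation = 0)
  m_r <- beta_to_m(repl_b$beta)
  d_r <- build_design(repl_b$phenotypes, covariates = c("age", "sex"))
  disc <- run_ewas(beta_to_m(disc_b$beta), build_design(disc_b$phenotypes,
                   covariates = c("age", "sex")))
  repl <- run_ewas(m_r, d_r)
  rep_out <- replicate_top_loci(disc, repl, disc_b$manifest, disc_b$beta,
                                k = 60)
  band <- qbinom(c(0.025, 0.975), rep_out$n_examined, 0.05)
  expect_gte(rep_out$n_nominal, band[1])
  expect_lte(rep_out$n_nominal, band[2])
})

test_that("candidate probe and gene analyses apply the right FDR scope", {
  res <- data.frame(probe_id = paste0("cg", 1:6), gene = c("A", "A", "A", "B", "C", ""),
                    coef = rnorm(6), p = c(0.01, 0.5, 0.9, 0.02, 0.7, 0.001),
                    stringsAsFactors = FALSE)
  # single candidate: adjusted equals raw
  one <- candidate_probe_analysis(res, "cg4")
  expect_equal(one$table$p_adj, 0.02)
  # missing candidates reported, not fatal
  out <- candidate_probe_analysis(res, c("cg1", "cgX"))
  expect_equal(out$missing, "cgX")
  expect_equal(out$table$p_adj, 0.02)  # 0.01 * 2 / 1

  man <- data.frame(probe_id = paste0("cg", 1:6),
                    chr = "chr1", pos = 1:6 * 1000,
                    gene = c("A", "A", "A", "B", "C", ""),
                    on_450k = TRUE, on_epic = TRUE, snps = "",
                    stringsAsFactors = FALSE)
  g <- candidate_gene_analysis(res, c("A", "B", "ZZZ"), man)
  # gene A: BH over {0.01, 0.5, 0.9} -> best adjusted 0.03 at cg1
  expect_equal(g$p_adj[g$gene == "A"], 0.03)
  expect_equal(g$best_probe[g$gene == "A"], "cg1")
  expect_equal(g$p_adj[g$gene == "B"], 0.02)  # single probe: raw
  expect_equal(g$n_probes[g$gene == "ZZZ"], 0)
})

test_that("a causal probe wins its gene-wide FDR among null siblings", {
  set.seed(35)
  wins <- 0L
  for (rep in 1:10) {
    n <- 200
    grp <- rep(0:1, each = n / 2)
    m <- matrix(rnorm(21 * n), 21, n)
    m[1, ] <- m[1, ] + 0.5 * grp
    rownames(m) <- paste0("cg", 1:21)
    colnames(m) <- paste0("s", 1:n)
    X <- cbind(`(Intercept)` = 1, ptsd = grp)
    res <- run_ewas(m, X, moderate = FALSE)
    man <- data.frame(probe_id = paste0("cg", 1:21), chr = "chr1",
                      pos = 1:21, gene = "G", on_450k = TRUE, on_epic = TRUE,
                      snps = "", stringsAsFactors = FALSE)
    g <- candidate_gene_analysis(res, "G", man)
    if (g$best_probe == "cg1") wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
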