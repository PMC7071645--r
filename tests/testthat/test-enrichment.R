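toy_manifest <- function(genes) {
  data.frame(probe_id = sprintf("cg%03d", seq_along(genes)), chr = "chr1",
             pos = seq_along(genes) * 1000, gene = genes,
             on_450k = TRUE, on_epic = TRUE, snps = "",
             stringsAsFactors = FALSE)
}

test_that("top-k gene bookkeeping matches construction", {
  genes <- c("A", "A", "B", "C", "C", "C", "", "D;E")
  man <- toy_manifest(genes)
  res <- data.frame(probe_id = man$probe_id, gene = genes,
                    coef = 1, p = seq(0.01, 0.08, by = 0.01),
                    stringsAsFactors = FALSE)
  out <- top_k_gene_list(res, man, k = 3)
  expect_setequal(out$significant, c("A", "B"))
  expect_setequal(out$universe, c("A", "B", "C", "D", "E"))
  expect_equal(out$probes_per_gene[["A"]], 2L)
  expect_equal(out$probes_per_gene[["C"]], 3L)
  expect_equal(out$probes_per_gene[["D"]], 1L)  # multi-gene probe counts for each
  # k = all probes: significant set equals universe
  all_out <- top_k_gene_list(res, man, k = nrow(res))
  expect_setequal(all_out$significant, all_out$universe)
})

test_that("bias weights are uniform in degenerate cases, monotone otherwise", {
  counts <- setNames(rep(3L, 10), paste0("g", 1:10))
  expect_true(all(probe_bias_weights(counts, c("g1", "g2")) == 1))
  counts2 <- setNames(1:10, paste0("g", 1:10))
  expect_warning(w0 <- probe_bias_weights(counts2, character()), "uniform")
  expect_true(all(w0 == 1))

  # selection probability proportional to probe count by construction
  set.seed(51)
  n <- 2000
  counts3 <- setNames(sample(1:20, n, replace = TRUE), paste0("g", 1:n))
  sig <- names(counts3)[runif(n) < counts3 / 40]
  w <- probe_bias_weights(counts3, sig)
  fit_by_count <- tapply(w, counts3, mean)
  expect_true(all(diff(fit_by_count) > -1e-9))  # monotone in probe count
  truth_by_count <- (as.numeric(names(fit_by_count)) / 40)
  expect_gt(stats::cor(fit_by_count, truth_by_count), 0.9)
})

test_that("Wallenius tail equals Fisher exact under unit odds", {
  for (rep in 1:60) {
    set.seed(rep)
    N <- sample(5:15, 1)
    m1 <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    x <- sample(0:min(m1, n), 1)
    w <- methewas:::wallenius_upper_tail(x, m1, N - m1, n, 1, 1)
    f <- stats::phyper(x - 1, m1, N - m1, n, lower.tail = FALSE)
    expect_lt(abs(w - f), 1e-9)
  }
})

test_that("Wallenius tail matches Monte-Carlo sampling under biased odds", {
  set.seed(52)
  m1 <- 6; m2 <- 10; n <- 7; w1 <- 2; w2 <- 1
  n_draws <- 2e5
  draws <- replicate(n_draws, {
    reds <- m1; whites <- m2; x <- 0L
    for (t in 1:n) {
      pr <- w1 * reds / (w1 * reds + w2 * whites)
      if (runif(1) < pr) { reds <- reds - 1L; x <- x + 1L } else whites <- whites - 1L
    }
    x
  })
  for (xo in 2:5) {
    exact <- methewas:::wallenius_upper_tail(xo, m1, m2, n, w1, w2)
    mc <- mean(draws >= xo)
    se <- sqrt(mc * (1 - mc) / n_draws)
    expect_lt(abs(exact - mc), 3 * se + 1e-12)
  }
})

test_that("set test handles degenerate sets and exhaustive small cases", {
  uni <- paste0("g", 1:20)
  sig <- paste0("g", 1:5)
  # set = universe: p = 1
  expect_equal(wallenius_set_test(uni, uni, sig)$p, 1)
  # disjoint set flagged with p = 1
  dis <- wallenius_set_test(c("zz1", "zz2"), uni, sig)
  expect_true(dis$disjoint)
  expect_equal(dis$p, 1)
  # uniform odds, universe 20, set 5, DE 5, overlap 3: hypergeometric tail
  out <- wallenius_set_test(paste0("g", c(1, 2, 3, 10, 11)), uni, sig)
  expect_equal(out$n_overlap, 3L)
  expect_equal(out$p, stats::phyper(2, 5, 15, 5, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("enrichment pipeline finds a constructed enriched set", {
  cfg <- tiny_config(n_probes = 700, n_cases = 150, n_controls = 100,
                     n_causal_probes = 25, causal_effect_m = 0.8, seed = 55)
  b <- simulate_blood_cohort(cfg)
  m <- beta_to_m(b$beta)
  d <- build_design(b$phenotypes, covariates = c("age", "sex"))
  keep <- probe_range_filter(b$beta)$retained
  res <- run_ewas(m[keep, ], d)
  sets <- synthetic_gene_sets(b$manifest, b$truth, n_sets = 15, seed = 3)
  out <- run_enrichment(res, b$manifest, sets, k = 60)
  expect_equal(out$set[1], "SPIKED")
  expect_true(all(out$n_de <= out$n_genes))
  expect_equal(out$p_adj, bh_adjust(out$p, m_total = nrow(out)),
               tolerance = 1e-12)
  # single set: adjusted equals raw
  one <- run_enrichment(res, b$manifest, sets["SPIKED"], k = 60)
  expect_equal(one$p_adj, one$p)
})

test_that("enrichment p is invariant to relabelling outside memberships", {
  uni <- paste0("g", 1:12)
  sig <- paste0("g", c(1, 2, 3, 7))
  odds <- setNames(rep(c(2, 1), each = 6), uni)
  set1 <- paste0("g", c(1, 2, 5))
  p1 <- wallenius_set_test(set1, uni, sig, odds)$p
  # permute labels while preserving set membership, significance and odds
  perm <- c(g1 = "g2", g2 = "g1", g5 = "g6", g6 = "g5")
  relabel <- function(x) ifelse(x %in% names(perm), perm[x], x)
  odds2 <- setNames(odds, relabel(names(odds)))
  p2 <- wallenius_set_test(relabel(set1), uni, relabel(sig), odds2)$p
  expect_equal(p1, p2, tolerance = 1e-12)
})
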