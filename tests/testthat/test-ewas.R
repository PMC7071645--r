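test_that("build_design validates rank and handles the cell-fraction simplex", {
  ph <- data.frame(sample_id = c("a", "b", "c", "d"),
                   subject_id = c("a", "b", "c", "d"),
                   ptsd = c(1, 0, 1, 0), age = c(30, 40, 50, 60),
                   sex = c(0, 1, 0, 1))
  d <- build_design(ph, covariates = character(), use_pcs = FALSE)
  expect_equal(colnames(d$X), c("(Intercept)", "ptsd"))
  expect_equal(qr(d$X)$rank, 2)

  cf <- matrix(c(0.6, 0.3, 0.5, 0.2, 0.4, 0.7, 0.5, 0.8), 4, 2,
               dimnames = list(ph$sample_id, c("t1", "t2")))
  d2 <- build_design(ph, covariates = character(), use_pcs = FALSE,
                     cell_fractions = cf)
  # one simplex column dropped: no rank deficiency, one cell column kept
  expect_equal(sum(grepl("^cell_", colnames(d2$X))), 1)

  ph$dup <- ph$ptsd
  expect_error(build_design(ph, covariates = "dup", use_pcs = FALSE),
               "rank deficient.*dup")
})

test_that("per-probe OLS recovers exact and closed-form cases", {
  X <- cbind(`(Intercept)` = 1, ptsd = c(1, 1, 0, 0, 1, 0))
  y <- 2 * X[, 2] + 1
  f <- fit_probe_ols(y, X)
  expect_equal(f$coef, 2)
  expect_equal(f$sigma2, 0)
  # balanced two-group design: coefficient is the difference of group means
  set.seed(1)
  y2 <- rnorm(6)
  f2 <- fit_probe_ols(y2, X)
  expect_equal(f2$coef, mean(y2[X[, 2] == 1]) - mean(y2[X[, 2] == 0]))
  expect_error(fit_probe_ols(y[1:2], X[1:2, ]), "more observations")
})

test_that("OLS matches the normal-equations oracle on random instances", {
  for (rep in 1:20) {
    set.seed(rep)
    n <- 30; p <- 4
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- c("(Intercept)", paste0("x", 1:(p - 1)))
    y <- rnorm(n)
    f <- fit_probe_ols(y, X, coef_name = "x1")
    beta_oracle <- solve(t(X) %*% X, t(X) %*% y)
    expect_lt(abs(f$coef - beta_oracle[2]), 1e-10)
    s2_oracle <- sum((y - X %*% beta_oracle)^2) / (n - p)
    expect_lt(abs(f$sigma2 - s2_oracle), 1e-10)
  }
})

test_that("vectorized fits agree with the single-probe path", {
  b <- tiny_blood()
  m <- beta_to_m(b$beta)[1:25, ]
  d <- build_design(b$phenotypes, covariates = c("age", "sex"))
  all_fits <- methewas:::fit_all_probes(m, d$X)
  one <- fit_probe_ols(m[7, rownames(d$X)], d$X)
  expect_equal(all_fits$coef[7], one$coef, tolerance = 1e-12)
  expect_equal(all_fits$se[7], one$se, tolerance = 1e-12)
  expect_equal(all_fits$sigma2[7], one$sigma2, tolerance = 1e-12)
})

test_that("empirical-Bayes moderation recovers a known variance prior", {
  set.seed(3)
  d0 <- 4; s0_2 <- 2; d <- 20; n <- 50000
  sigma2 <- d0 * s0_2 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, d) / d
  mod <- eb_moderate(s2, d)
  expect_lt(abs(mod$d0 - d0) / d0, 0.10)
  expect_lt(abs(mod$s0_2 - s0_2) / s0_2, 0.05)
  # posterior variances are a convex combination of sample and prior
  expect_true(all(mod$post_var >= pmin(s2, mod$s0_2) - 1e-12))
  expect_true(all(mod$post_var <= pmax(s2, mod$s0_2) + 1e-12))
})

test_that("moderation degenerates correctly", {
  mod <- eb_moderate(rep(1, 100), 10)
  expect_identical(mod$d0, Inf)
  expect_true(all(mod$post_var == 1))
  one <- eb_moderate(2.5, 10)
  expect_equal(one$post_var, 2.5)
  expect_error(eb_moderate(c(1, -1), 10), "positive")
})

test_that("moderation agrees with the established moderated-t implementation", {
  skip_if_not_installed("limma")
  set.seed(4)
  s2 <- rchisq(500, 8) / 8 * (2 / rchisq(500, 5) * 5)
  mod <- eb_moderate(s2, 12)
  sq <- limma::squeezeVar(s2, 12)
  expect_equal(mod$d0, sq$df.prior, tolerance = 1e-8)
  expect_equal(mod$s0_2, sq$var.prior, tolerance = 1e-8)
  expect_equal(mod$post_var, sq$var.post, tolerance = 1e-8)
})

test_that("bh_adjust equals the brute-force step-up on random subsets", {
  for (rep in 1:40) {
    set.seed(rep)
    k <- sample(1:8, 1)
    p <- runif(k)
    m <- k + sample(0:20, 1)
    expect_equal(bh_adjust(p, m_total = m), bh_oracle(p, m), tolerance = 1e-12)
  }
  # order invariance
  p <- runif(8)
  ord <- sample(8)
  expect_equal(bh_adjust(p, 30)[ord], bh_adjust(p[ord], 30))
  expect_equal(bh_adjust(0.05, 1), 0.05)
  expect_error(bh_adjust(c(0.5, 0.2), m_total = 1), "at least")
  expect_error(bh_adjust(c(0, 0.5)), "0, 1")
})

test_that("genomic inflation is calibrated and detects scaling", {
  expect_equal(genomic_inflation(rep(0.5, 200)), 1.0)
  set.seed(6)
  chi <- rchisq(10000, 1)
  p_null <- pchisq(chi, 1, lower.tail = FALSE)
  expect_lt(abs(genomic_inflation(p_null) - 1), 0.05)
  p_infl <- pchisq(1.5 * chi, 1, lower.tail = FALSE)
  expect_lt(abs(genomic_inflation(p_infl) - 1.5), 0.05)
  expect_error(genomic_inflation(runif(50)), "100")
})

test_that("null-simulation EWAS is calibrated", {
  cfg <- tiny_config(n_probes = 2000, n_cases = 80, n_controls = 80,
                     causal_effect_m = 0, smoking_effect_m = 0,
                     meqtl_effect_m = 0, low_var_fraction = 0, seed = 13)
  b <- simulate_blood_cohort(cfg)
  m <- beta_to_m(b$beta)
  cells <- estimate_fractions(b$beta, b$cell_reference)
  d <- build_design(b$phenotypes, covariates = c("age", "sex"),
                    cell_fractions = cells$fractions)
  res <- run_ewas(m, d)
  expect_gt(attr(res, "lambda"), 0.9)
  expect_lt(attr(res, "lambda"), 1.1)
  # uniform p-values: KS against uniform
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
  # type-I error at alpha = 0.05 inside the binomial 99% band
  band <- qbinom(c(0.005, 0.995), nrow(res), 0.05) / nrow(res)
  rate <- mean(res$p < 0.05)
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("spiked-simulation EWAS finds mostly true positives at FDR 0.05", {
  cfg <- tiny_config(n_probes = 1000, n_cases = 378, n_controls = 135,
                     n_causal_probes = 50, causal_effect_m = 0.5,
                     low_var_fraction = 0, seed = 14)
  b <- simulate_blood_cohort(cfg)
  m <- beta_to_m(b$beta)
  d <- build_design(b$phenotypes, covariates = c("age", "sex"))
  res <- run_ewas(m, d)
  hits <- res$probe_id[res$p_adj < 0.05]
  expect_gt(length(hits), 0)
  expect_gte(mean(hits %in% names(b$truth$causal)), 0.8)
})
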