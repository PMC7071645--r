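make_paired <- function(ns, sigma_b, sigma_e, effect = 0.5, seed = 1) {
  set.seed(seed)
  subj <- rep(seq_len(ns), each = 2)
  ptsd <- rep(rbinom(ns, 1, 0.5), each = 2)
  x <- rnorm(2 * ns)
  X <- cbind(`(Intercept)` = 1, ptsd = ptsd, x = x)
  y <- effect * ptsd + 0.3 * x +
    rep(rnorm(ns, sd = sigma_b), each = 2) + rnorm(2 * ns, sd = sigma_e)
  list(y = y, X = X, subject = subj)
}

test_that("zero subject variance reduces to pooled OLS", {
  d <- make_paired(40, sigma_b = 0, sigma_e = 1, seed = 2)
  f <- fit_random_intercept_probe(d$y, d$X, d$subject)
  ols <- fit_probe_ols(d$y, d$X)
  expect_lt(abs(f$coef - ols$coef), 1e-6)
  expect_lt(f$icc, 0.15)
})

test_that("GLS at the true variance ratio is matched by the REML profile", {
  # oracle: GLS with the generating lambda fixed, computed from the
  # explicit whitened normal equations
  d <- make_paired(60, sigma_b = 0.8, sigma_e = 0.6, seed = 3)
  lambda_hat_fit <- fit_random_intercept_probe(d$y, d$X, d$subject)
  gls_oracle <- function(lambda) {
    V <- diag(2 * 60)
    for (s in unique(d$subject)) {
      idx <- which(d$subject == s)
      V[idx, idx] <- V[idx, idx] + lambda
    }
    b <- solve(t(d$X) %*% solve(V, d$X), t(d$X) %*% solve(V, d$y))
    drop(b)[2]
  }
  # at the REML-estimated ratio, the closed-form GLS equals the fit
  lam <- lambda_hat_fit$sigma_b2 / lambda_hat_fit$sigma_e2
  expect_lt(abs(gls_oracle(lam) - lambda_hat_fit$coef), 1e-8)
})

test_that("REML matches a grid-search oracle on a small instance", {
  d <- make_paired(25, sigma_b = 0.7, sigma_e = 0.5, seed = 4)
  f <- fit_random_intercept_probe(d$y, d$X, d$subject)
  grid <- seq(0.001, 10, by = 1e-3)
  crit <- vapply(grid, function(l) methewas:::reml_criterion(l, d$y, d$X, d$subject),
                 numeric(1))
  lam_grid <- grid[which.min(crit)]
  expect_lt(abs(f$sigma_b2 / f$sigma_e2 - lam_grid), 2e-3)
})

test_that("estimates agree with the established mixed-model package", {
  skip_if_not_installed("lme4")
  d <- make_paired(50, sigma_b = 0.8, sigma_e = 0.6, seed = 5)
  f <- fit_random_intercept_probe(d$y, d$X, d$subject)
  df <- data.frame(y = d$y, ptsd = d$X[, 2], x = d$X[, 3], subj = d$subject)
  lf <- lme4::lmer(y ~ ptsd + x + (1 | subj), data = df, REML = TRUE)
  expect_equal(f$coef, unname(lme4::fixef(lf)[2]), tolerance = 1e-5)
  expect_equal(f$se, sqrt(as.matrix(stats::vcov(lf))[2, 2]), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(f$sigma_b2, vc[1], tolerance = 1e-4)
  expect_equal(f$sigma_e2, vc[2], tolerance = 1e-4)
})

test_that("identical within-subject pairs push residual variance to zero", {
  set.seed(6)
  ns <- 30
  subj <- rep(seq_len(ns), each = 2)
  vals <- rnorm(ns, sd = 2)
  y <- vals[subj]
  X <- cbind(`(Intercept)` = 1, ptsd = rep(rbinom(ns, 1, 0.5), each = 2))
  f <- fit_random_intercept_probe(y, X, subj)
  expect_gt(f$icc, 0.99)
})

test_that("ICC and coefficient are recovered from simulated brain cohorts", {
  iccs <- coefs <- numeric(5)
  for (r in 1:5) {
    cfg <- tiny_config(n_probes = 150, n_causal_probes = 10,
                       causal_effect_m = 0.3, brain_icc = 0.6,
                       n_brain_cases = 42, n_brain_controls = 30,
                       seed = 100 + r)
    br <- simulate_brain_cohort(cfg)
    m <- beta_to_m(br$beta)
    ph <- br$phenotypes
    ph$region_vmpfc <- as.integer(ph$region == "vmPFC")
    d <- build_design(ph, covariates = c("age", "sex", "region_vmpfc"))
    subj <- ph$subject_id[match(rownames(d$X), ph$sample_id)]
    causal <- intersect(names(br$truth$causal), rownames(m))
    fits <- lapply(causal[1:5], function(pid)
      fit_random_intercept_probe(m[pid, rownames(d$X)], d$X, subj))
    iccs[r] <- mean(vapply(fits, `[[`, numeric(1), "icc"))
    coefs[r] <- mean(vapply(fits, `[[`, numeric(1), "coef"))
  }
  expect_lt(abs(mean(iccs) - 0.6), 0.1)
  expect_lt(abs(mean(coefs) - 0.3), 0.05)
})

test_that("joint modelling is at least as precise as one region alone", {
  d <- make_paired(40, sigma_b = 0.6, sigma_e = 0.8, seed = 7)
  joint <- fit_random_intercept_probe(d$y, d$X, d$subject)
  one_region <- seq(1, 80, by = 2)
  single <- fit_probe_ols(d$y[one_region], d$X[one_region, ])
  expect_lte(joint$se, single$se)
})

test_that("brain EWAS applies BH over the examined probes and fits regions", {
  br <- fixture("tiny_brain", simulate_brain_cohort(tiny_config()))
  m <- beta_to_m(br$beta)
  ph <- br$phenotypes
  ph$region_vmpfc <- as.integer(ph$region == "vmPFC")
  d <- build_design(ph, covariates = c("age", "sex", "smoking_status",
                                       "region_vmpfc"))
  subj <- ph$subject_id[match(rownames(d$X), ph$sample_id)]
  probes <- rownames(m)[1:20]
  res <- run_brain_ewas(m, probes, d, subj, manifest = br$manifest)
  expect_equal(nrow(res), 20)
  expect_equal(res$p_adj, bh_adjust(res$p, m_total = 20))
  expect_error(run_brain_ewas(m, "cg9999999", d, subj), "absent")

  # a single examined probe: adjusted equals raw
  res1 <- run_brain_ewas(m, probes[1], d, subj)
  expect_equal(res1$p_adj, res1$p)

  reg <- per_region_fit(m[probes[1], rownames(d$X)], d$X,
                        ph$region[match(rownames(d$X), ph$sample_id)], "dlPFC")
  expect_true(is.finite(reg$p))
  expect_error(per_region_fit(m[probes[1], rownames(d$X)], d$X,
                              ph$region[match(rownames(d$X), ph$sample_id)],
                              "cerebellum"), "no samples")
})

test_that("per-region coefficients are consistent under shared effects", {
  cfg <- tiny_config(n_probes = 200, n_causal_probes = 15,
                     causal_effect_m = 0.5, seed = 44)
  br <- simulate_brain_cohort(cfg)
  m <- beta_to_m(br$beta)
  ph <- br$phenotypes
  d <- build_design(ph, covariates = c("age", "sex"))
  region <- ph$region[match(rownames(d$X), ph$sample_id)]
  causal <- intersect(names(br$truth$causal), rownames(m))
  within <- vapply(causal, function(pid) {
    a <- per_region_fit(m[pid, rownames(d$X)], d$X, region, "dlPFC")
    b <- per_region_fit(m[pid, rownames(d$X)], d$X, region, "vmPFC")
    abs(a$coef - b$coef) <= 2 * sqrt(a$se^2 + b$se^2)
  }, logical(1))
  expect_gte(mean(within), 0.9)
})
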