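#' Build the EWAS design matrix
#'
#' Assembles intercept, PTSD indicator, and covariate columns from a
#' phenotype table, keeping complete cases only and validating rank. Cell
#' fractions live on a simplex, so one cell type (the largest-mean one) is
#' dropped to avoid exact collinearity with the intercept.
#'
#' @param phenotypes Phenotype data.frame (see [read_phenotypes()]).
#' @param covariates Character vector of phenotype columns to adjust for, in
#'   addition to ancestry PCs (all `pc<k>` columns are included
#'   automatically unless `use_pcs = FALSE`).
#' @param cell_fractions Optional sample-by-cell-type matrix of estimated
#'   fractions (rownames are sample ids); one column is dropped.
#' @param outcome Name of the binary outcome column (default `"ptsd"`).
#' @param use_pcs Include `pc<k>` columns (default TRUE).
#' @return List with `X` (numeric design matrix, rownames sample ids, first
#'   two columns intercept and the outcome), `sample_ids`, and `n_dropped`
#'   (incomplete cases removed).
#' @export
build_design <- function(phenotypes, covariates = c("age", "sex"),
                         cell_fractions = NULL, outcome = "ptsd",
                         use_pcs = TRUE) {
  require_columns(phenotypes, c("sample_id", outcome), "phenotype table")
  pcs <- if (use_pcs) grep("^pc[0-9]+$", colnames(phenotypes), value = TRUE) else character()
  covariates <- union(covariates, pcs)
  require_columns(phenotypes, covariates, "phenotype table")
  X <- cbind(`(Intercept)` = 1, as.matrix(phenotypes[c(outcome, covariates)]))
  colnames(X)[2L] <- outcome
  rownames(X) <- phenotypes$sample_id
  if (!is.null(cell_fractions)) {
    cf <- cell_fractions[phenotypes$sample_id, , drop = FALSE]
    drop_type <- colnames(cf)[which.max(colMeans(cf, na.rm = TRUE))]
    cf <- cf[, setdiff(colnames(cf), drop_type), drop = FALSE]
    colnames(cf) <- paste0("cell_", colnames(cf))
    X <- cbind(X, cf)
  }
  complete <- stats::complete.cases(X)
  X <- X[complete, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  list(X = X, sample_ids = rownames(X), n_dropped = sum(!complete))
}

#' Per-probe ordinary least squares for one response row
#'
#' Fits `m_row ~ design` by OLS and reports the coefficient of interest
#' (by default the second design column, the case/control indicator), its
#' standard error, the residual variance and residual degrees of freedom,
#' and the pre-moderation two-sided t-test p-value.
#'
#' @param m_row Numeric response vector (one probe's M-values), aligned with
#'   the design rows; `NA`s are dropped together with their rows.
#' @param design Numeric design matrix including the intercept.
#' @param coef_name Column of interest (default the second column).
#' @return List: `coef`, `se`, `sigma2`, `df`, `t`, `p`, `n`.
#' @export
fit_probe_ols <- function(m_row, design, coef_name = colnames(design)[2L]) {
  ok <- !is.na(m_row)
  y <- m_row[ok]
  X <- design[ok, , drop = FALSE]
  if (length(y) <= ncol(X)) {
    stop("need more observations than design columns", call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  j <- match(coef_name, colnames(design))
  se <- sqrt(sigma2 * XtXinv[j, j])
  tval <- if (se > 0) fit$coefficients[j] / se else sign(fit$coefficients[j]) * Inf
  list(coef = unname(fit$coefficients[j]), se = unname(se), sigma2 = sigma2,
       df = df, t = unname(tval),
       p = 2 * stats::pt(-abs(tval), df), n = length(y))
}

# Vectorized OLS for all probes sharing one design (complete rows only).
fit_all_probes <- function(m, design, coef_name = colnames(design)[2L]) {
  if (!is.null(rownames(design)) && !is.null(colnames(m))) {
    m <- m[, rownames(design), drop = FALSE]
  }
  qrX <- qr(design)
  p <- ncol(design)
  df <- nrow(design) - p
  if (df < 1L) stop("need more samples than design columns", call. = FALSE)
  coefs <- t(qr.coef(qrX, t(m)))
  fitted <- coefs %*% t(design)
  rss <- rowSums((m - fitted)^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  j <- match(coef_name, colnames(design))
  se <- sqrt(sigma2 * XtXinv[j, j])
  data.frame(probe_id = rownames(m), coef = coefs[, j], se = se,
             sigma2 = sigma2, df = df, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Shrinks per-probe residual variances toward an ensemble prior by fitting a
#' scaled inverse-chi-square prior with `d0` degrees of freedom and scale
#' `s0^2` to the observed variances, via the method of moments on log
#' variances: the excess spread of `log(s^2)` beyond what `trigamma(df/2)`
#' explains identifies `trigamma(d0/2)`, inverted numerically; the mean
#' identifies `s0^2`. The posterior variance for each probe is the
#' df-weighted average `(d0*s0^2 + df*s^2) / (d0 + df)`, and the moderated
#' t-statistic uses it with `d0 + df` degrees of freedom. When the observed
#' variances are no more dispersed than sampling alone predicts, `d0` is
#' infinite and every posterior variance equals `s0^2`.
#'
#' @param sigma2 Per-probe residual variances (positive).
#' @param df Residual degrees of freedom (scalar or per-probe).
#' @return List: `d0`, `s0_2`, `post_var` (per-probe posterior variances),
#'   `df_total` (moderated df, `d0 + df`).
#' @export
eb_moderate <- function(sigma2, df) {
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop("variances must be positive and finite for moderation", call. = FALSE)
  }
  n <- length(sigma2)
  df <- rep_len(df, n)
  if (n == 1L) {
    return(list(d0 = 0, s0_2 = sigma2, post_var = sigma2, df_total = df))
  }
  z <- log(sigma2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(z) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    # no excess dispersion beyond sampling: infinite prior df, and the
    # ensemble scale is simply the mean variance
    d0 <- Inf
    s0_2 <- mean(sigma2)
    post_var <- rep(s0_2, n)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    post_var <- (d0 * s0_2 + df * sigma2) / (d0 + df)
  }
  list(d0 = d0, s0_2 = s0_2, post_var = post_var, df_total = d0 + df)
}

#' Benjamini-Hochberg adjusted p-values with an explicit test count
#'
#' Step-up FDR adjustment \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1, where `m = m_total` may exceed the number of p-values
#' supplied. This supports adjusting a printed subset of results (e.g. a
#' table of top loci) against the full number of tests performed.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param m_total Total number of tests (default `length(p)`).
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(1e-6, 0.01, 0.04), m_total = 100)
bh_adjust <- function(p, m_total = length(p)) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  assert_count(m_total, "m_total", min = 1L)
  if (m_total < length(p)) {
    stop("m_total must be at least the number of p-values", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH", n = m_total)
}

#' Genomic inflation factor lambda
#'
#' The ratio of the median observed association statistic (as a 1-df
#' chi-square quantile of the p-values) to its null expectation 0.4549364.
#' Values near 1 indicate a calibrated test; values well above 1 indicate
#' inflation from confounding or miscalibration.
#'
#' @param p P-values from at least 100 tests.
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100L) stop("lambda needs >= 100 p-values", call. = FALSE)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Run the per-probe EWAS
#'
#' Fits every probe by OLS against a shared design, applies empirical-Bayes
#' variance moderation (optional), computes two-sided p-values and
#' Benjamini-Hochberg adjusted p-values, and returns a result table sorted
#' by p. Ties in ranking are broken by descending absolute coefficient, then
#' probe id, so top-k selections are deterministic.
#'
#' @param m Probe-by-sample M-value matrix.
#' @param design Design matrix from [build_design()] (`$X`) or a plain
#'   matrix whose second column is the case/control indicator.
#' @param m_total Total test count for the FDR adjustment (default: number
#'   of probes analyzed). Allows adjusting a pre-filtered matrix against the
#'   full analysis count.
#' @param moderate Apply empirical-Bayes moderation (default TRUE).
#' @param manifest Optional manifest; when given, gene symbols are merged in.
#' @return data.frame (`EwasResultTable`): `probe_id`, `gene`, `coef`, `se`,
#'   `t`, `df`, `p`, `p_adj`, `n`, sorted by ascending p. Attributes:
#'   `lambda` (genomic inflation, if >= 100 probes) and `moderation`
#'   (the [eb_moderate()] fit).
#' @export
run_ewas <- function(m, design, m_total = NULL, moderate = TRUE,
                     manifest = NULL) {
  if (is.list(design) && !is.null(design$X)) design <- design$X
  fits <- fit_all_probes(m, design)
  if (moderate && nrow(fits) >= 10L) {
    mod <- eb_moderate(fits$sigma2, fits$df)
    scale <- sqrt(mod$post_var / fits$sigma2)
    tval <- fits$coef / (fits$se * scale)
    df_t <- mod$df_total
    se_out <- fits$se * scale
  } else {
    mod <- NULL
    tval <- fits$coef / fits$se
    df_t <- fits$df
    se_out <- fits$se
  }
  p <- 2 * stats::pt(-abs(tval), df_t)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  if (is.null(m_total)) m_total <- nrow(fits)
  res <- data.frame(
    probe_id = fits$probe_id,
    gene = if (!is.null(manifest)) {
      manifest$gene[match(fits$probe_id, manifest$probe_id)]
    } else NA_character_,
    coef = fits$coef, se = se_out, t = tval,
    df = if (length(df_t) == 1L) rep(df_t, nrow(fits)) else df_t,
    p = p, p_adj = bh_adjust(p, m_total = m_total),
    n = nrow(design), stringsAsFactors = FALSE
  )
  res <- res[order(res$p, -abs(res$coef), res$probe_id), , drop = FALSE]
  rownames(res) <- NULL
  if (nrow(res) >= 100L) attr(res, "lambda") <- genomic_inflation(res$p)
  attr(res, "moderation") <- mod
  attr(res, "m_total") <- m_total
  res
}
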