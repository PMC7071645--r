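# Random-intercept linear mixed model for paired brain-region methylation.
#
# Model per probe: y = X beta + b[subject] + e, with subject intercepts
# b ~ N(0, sigma_b^2) capturing the correlation between the two prefrontal
# cortex regions of the same donor, and e ~ N(0, sigma_e^2). With
# lambda = sigma_b^2 / sigma_e^2, the covariance of a subject's block of
# observations is sigma_e^2 (I + lambda J), which has closed-form inverse
# and determinant, so the REML criterion can be profiled down to a
# one-dimensional search over lambda.

# Whiten per-subject blocks: multiply by (I + lambda J)^{-1/2}.
whiten_blocks <- function(y, X, subject, lambda) {
  Xw <- X
  yw <- y
  logdet <- 0
  for (s in unique(subject)) {
    idx <- which(subject == s)
    k <- length(idx)
    a <- (1 / sqrt(1 + k * lambda) - 1) / k
    logdet <- logdet + log(1 + k * lambda)
    yw[idx] <- y[idx] + a * sum(y[idx])
    Xw[idx, ] <- X[idx, , drop = FALSE] +
      matrix(a * colSums(X[idx, , drop = FALSE]), k, ncol(X), byrow = TRUE)
  }
  list(y = yw, X = Xw, logdet = logdet)
}

reml_criterion <- function(lambda, y, X, subject) {
  w <- whiten_blocks(y, X, subject, lambda)
  qrX <- qr(w$X)
  rss <- sum(qr.resid(qrX, w$y)^2)
  n <- length(y)
  p <- ncol(X)
  R <- qr.R(qrX)
  # -2 profiled REML log-likelihood up to constants
  (n - p) * log(max(rss, 1e-300)) + w$logdet + 2 * sum(log(abs(diag(R))))
}

#' Fit a random-intercept mixed model for one probe
#'
#' REML estimation of the subject-intercept and residual variance
#' components by one-dimensional profiled optimization over their ratio,
#' with the fixed effects estimated by generalized least squares at the
#' optimum. The test for the case/control coefficient is a Wald t-test with
#' `n - p - q + 1` degrees of freedom (observations minus fixed-effect
#' columns minus subjects plus one), a conservative choice for the paired
#' two-region design.
#'
#' @param y M-values for one probe across all brain samples.
#' @param design Fixed-effect design matrix (first column intercept, second
#'   the case/control indicator), rows aligned with `y`.
#' @param subject Subject id per observation (repeats across regions).
#' @param coef_name Fixed-effect column tested (default the second column).
#' @return List (`MixedFitResult`): `coef`, `se`, `t`, `df`, `p`,
#'   `sigma_b2`, `sigma_e2`, `icc`, `converged`.
#' @export
fit_random_intercept_probe <- function(y, design, subject,
                                       coef_name = colnames(design)[2L]) {
  ok <- !is.na(y)
  y <- y[ok]
  X <- design[ok, , drop = FALSE]
  subject <- subject[ok]
  if (length(unique(subject)) < 2L || !any(duplicated(subject))) {
    stop("need >= 2 subjects with repeated observations", call. = FALSE)
  }
  crit <- function(loglam) reml_criterion(exp(loglam), y, X, subject)
  opt <- stats::optimize(crit, interval = c(-12, 12))
  cand <- c(exp(opt$minimum), 0)
  vals <- c(opt$objective, reml_criterion(0, y, X, subject))
  lambda <- cand[which.min(vals)]
  converged <- !(opt$minimum > 11.9)  # hit upper search bound
  w <- whiten_blocks(y, X, subject, lambda)
  qrX <- qr(w$X)
  beta <- qr.coef(qrX, w$y)
  rss <- sum(qr.resid(qrX, w$y)^2)
  n <- length(y)
  p <- ncol(X)
  q <- length(unique(subject))
  df <- n - p - q + 1L
  sigma_e2 <- rss / (n - p)
  sigma_b2 <- lambda * sigma_e2
  XtVinvX_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  j <- match(coef_name, colnames(design))
  se <- sqrt(sigma_e2 * XtVinvX_inv[j, j])
  tval <- beta[j] / se
  list(coef = unname(beta[j]), se = unname(se), t = unname(tval), df = df,
       p = 2 * stats::pt(-abs(tval), df),
       sigma_b2 = sigma_b2, sigma_e2 = sigma_e2,
       icc = if (sigma_b2 + sigma_e2 > 0) sigma_b2 / (sigma_b2 + sigma_e2) else 0,
       converged = converged)
}

#' Brain replication EWAS over a probe set
#'
#' Fits [fit_random_intercept_probe()] for each requested probe of a paired
#' brain cohort (two prefrontal-cortex regions per donor) and applies
#' Benjamini-Hochberg adjustment with `m_total` equal to the number of
#' probes examined.
#'
#' @param m Probe-by-sample brain M-value matrix.
#' @param probes Probe ids to examine (e.g. the top 100 discovery loci).
#' @param design Fixed-effect design matrix (from [build_design()] `$X` or
#'   a plain matrix), rows named by sample id.
#' @param subject Subject id per design row.
#' @param manifest Optional manifest for gene annotation.
#' @return `EwasResultTable` data.frame sorted by p, with `icc` and
#'   `converged` columns.
#' @export
run_brain_ewas <- function(m, probes, design, subject, manifest = NULL) {
  if (is.list(design) && !is.null(design$X)) design <- design$X
  missing <- setdiff(probes, rownames(m))
  if (length(missing)) {
    stop("probe(s) absent from brain matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  m <- m[probes, rownames(design), drop = FALSE]
  fits <- lapply(probes, function(pid) {
    f <- fit_random_intercept_probe(m[pid, ], design, subject)
    data.frame(probe_id = pid,
               gene = if (!is.null(manifest)) {
                 manifest$gene[match(pid, manifest$probe_id)]
               } else NA_character_,
               coef = f$coef, se = f$se, t = f$t, df = f$df, p = f$p,
               icc = f$icc, converged = f$converged,
               n = nrow(design), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, fits)
  res$p_adj <- bh_adjust(res$p, m_total = length(probes))
  res <- res[order(res$p, -abs(res$coef), res$probe_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-region follow-up fit
#'
#' Ordinary least-squares fit of one probe within a single brain region,
#' with the same fixed-effect covariates as the joint model, to check that
#' a joint-model association is consistent across regions.
#'
#' @param y Probe M-values across all brain samples.
#' @param design Fixed-effect design matrix, rows aligned with `y`.
#' @param region Region label per row.
#' @param which_region Region to fit (e.g. `"dlPFC"`).
#' @return List as [fit_probe_ols()].
#' @export
per_region_fit <- function(y, design, region, which_region) {
  idx <- region == which_region
  if (!any(idx)) stop("no samples in region: ", which_region, call. = FALSE)
  X <- design[idx, , drop = FALSE]
  # covariates constant within the region (e.g. the region indicator)
  # would alias the intercept; drop them
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, function(v) stats::var(v) > 0))
  fit_probe_ols(y[idx], X[, keep, drop = FALSE])
}
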