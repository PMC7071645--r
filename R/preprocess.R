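#' Convert methylation beta values to M-values
#'
#' The M-value is the base-2 logit of the methylated proportion,
#' \eqn{M = \log_2(\beta / (1 - \beta))}. Linear modelling of methylation is
#' performed on the M scale, where effects are closer to additive and the
#' variance is less dependent on the mean.
#'
#' @param beta Numeric vector, matrix, or array of beta values, all strictly
#'   inside (0, 1). Values at exactly 0 or 1 are a domain error: clamping is
#'   the responsibility of the reader (see [read_beta_matrix()]).
#' @return Object of the same shape with M-values.
#' @seealso [m_to_beta()] for the inverse transform.
#' @export
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8)) # -2, 0, 2
beta_to_m <- function(beta) {
  bad <- !is.na(beta) & (beta <= 0 | beta >= 1)
  if (any(bad)) {
    stop(sprintf("beta values must lie strictly in (0, 1); %d value(s) do not",
                 sum(bad)), call. = FALSE)
  }
  log2(beta / (1 - beta))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()]: \eqn{\beta = 2^M / (1 + 2^M)}.
#'
#' @param m Numeric vector, matrix, or array of M-values.
#' @return Beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  # logistic on the base-2 scale; written to avoid overflow for large |m|
  stats::plogis(m * log(2))
}

#' Filter probes by beta-value range
#'
#' Low-variation probes have poor signal-to-noise and replicate poorly across
#' chips. A probe is excluded when the range (max minus min) of its beta
#' values across samples, computed over non-missing entries, is strictly less
#' than `min_range`. Probes whose range is exactly `min_range` are retained.
#' All-missing probes are excluded and counted separately.
#'
#' @param beta Numeric matrix of beta values, probes in rows (rownames are
#'   probe ids), samples in columns.
#' @param min_range Minimum beta range for retention (default 0.10).
#' @return A list with
#'   \item{retained}{character vector of retained probe ids,}
#'   \item{report}{a `FilterReport` list: `n_input`, `n_excluded_low_range`,
#'     `n_excluded_all_missing`, `n_retained`, and `range` (named per-probe
#'     range vector; `NA` for all-missing probes).}
#' @export
probe_range_filter <- function(beta, min_range = 0.10) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  if (ncol(beta) < 2L) stop("range filter needs at least 2 samples", call. = FALSE)
  rng <- apply(beta, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else max(x) - min(x)
  })
  all_missing <- is.na(rng)
  # strict-< exclusion; the 1e-12 guard keeps ranges that equal the
  # threshold up to floating-point rounding (e.g. 0.50 - 0.40)
  low <- !all_missing & rng < min_range - 1e-12
  retained <- rownames(beta)[!all_missing & !low]
  report <- list(
    n_input = nrow(beta),
    n_excluded_low_range = sum(low),
    n_excluded_all_missing = sum(all_missing),
    n_retained = length(retained),
    min_range = min_range,
    range = rng
  )
  stopifnot(report$n_input ==
    report$n_excluded_low_range + report$n_excluded_all_missing + report$n_retained)
  list(retained = retained, report = report)
}
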