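#' Compute the per-sample DNA-methylation smoking score
#'
#' A weighted sum of M-values at probes whose methylation responds to
#' cigarette smoke, with weights taken from an external smoking EWAS
#' (typically the top 39 smoking-associated probes). The score serves as a
#' molecular surrogate for smoking exposure and enters association models as
#' a covariate. Probes absent from the matrix are skipped with a warning so
#' that the score remains defined on any platform subset.
#'
#' @param m Probe-by-sample M-value matrix.
#' @param weights Named numeric vector (probe id -> weight), e.g. from
#'   [read_weights()].
#' @param standardize Z-score across samples (default TRUE, for
#'   design-matrix conditioning).
#' @param leave_out Probe ids to exclude from the calculation (supports
#'   sensitivity analyses in which a probe of interest is removed from its
#'   own covariate).
#' @return Named numeric vector of scores, one per sample.
#' @export
compute_smoking_score <- function(m, weights, standardize = TRUE,
                                  leave_out = character()) {
  weights <- weights[setdiff(names(weights), leave_out)]
  present <- intersect(names(weights), rownames(m))
  if (length(present) == 0L) {
    stop("no smoking-score probes present in the matrix", call. = FALSE)
  }
  if (length(present) < length(weights)) {
    warning(sprintf("%d of %d smoking-score probes absent from the matrix; skipped",
                    length(weights) - length(present), length(weights)))
  }
  score <- drop(crossprod(m[present, , drop = FALSE], weights[present]))
  names(score) <- colnames(m)
  if (standardize) {
    s <- stats::sd(score)
    if (s > 0) score <- (score - mean(score)) / s else score <- score - mean(score)
  }
  score
}

#' Validate a smoking score against smoking phenotypes
#'
#' Reports the two-sample t-test of the score by smoking status and the
#' Pearson correlation of the score with cigarettes per day.
#'
#' @param score Named numeric vector of scores (names are sample ids).
#' @param phenotypes Phenotype table with `sample_id` and, where available,
#'   `smoking_status` (binary) and `cigarettes_per_day`.
#' @return List: `status_p` (t-test p, or NA when a group is empty),
#'   `cigs_r`, `cigs_p`, `n_status`, `n_cigs`.
#' @export
validate_score <- function(score, phenotypes) {
  if (stats::sd(score, na.rm = TRUE) == 0) {
    stop("score is constant; correlation undefined", call. = FALSE)
  }
  ph <- phenotypes[match(names(score), phenotypes$sample_id), , drop = FALSE]
  out <- list(status_p = NA_real_, cigs_r = NA_real_, cigs_p = NA_real_,
              n_status = 0L, n_cigs = 0L)
  if (!is.null(ph$smoking_status)) {
    ok <- !is.na(ph$smoking_status) & !is.na(score)
    if (sum(ok) >= 3L && length(unique(ph$smoking_status[ok])) == 2L) {
      tt <- stats::t.test(score[ok] ~ ph$smoking_status[ok])
      out$status_p <- tt$p.value
      out$n_status <- sum(ok)
    }
  }
  if (!is.null(ph$cigarettes_per_day)) {
    ok <- !is.na(ph$cigarettes_per_day) & !is.na(score)
    if (sum(ok) >= 3L) {
      ct <- stats::cor.test(score[ok], ph$cigarettes_per_day[ok])
      out$cigs_r <- unname(ct$estimate)
      out$cigs_p <- ct$p.value
      out$n_cigs <- sum(ok)
    }
  }
  out
}
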