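# Post-hoc confounder checks for top loci: refits with extra covariates
# (depression, medication, alcohol), SNP-dosage adjustment, and direct
# meQTL tests.

#' Refit one probe with an additional covariate
#'
#' Augments the base design with one extra covariate column and refits by
#' OLS, reporting the case/control coefficient under augmentation. Rows
#' with a missing covariate are dropped (complete-case within the refit)
#' and the sample count is reported so refits remain auditable.
#'
#' @param y Probe M-values aligned with the base design rows.
#' @param design Base design matrix (first column intercept, second the
#'   case/control indicator).
#' @param covariate Numeric covariate vector aligned with the design rows.
#' @param name Column name for the covariate in the augmented design.
#' @return List as [fit_probe_ols()], plus `n` (samples used).
#' @export
refit_with_covariate <- function(y, design, covariate, name = "extra") {
  stopifnot(length(covariate) == nrow(design))
  ok <- !is.na(covariate) & !is.na(y)
  X <- cbind(design[ok, , drop = FALSE], covariate[ok])
  colnames(X)[ncol(X)] <- name
  if (qr(X)$rank < ncol(X)) {
    stop("augmented design is rank deficient (covariate '", name,
         "' is collinear)", call. = FALSE)
  }
  fit_probe_ols(y[ok], X)
}

#' Case/control association adjusted for nearby SNP dosages
#'
#' Adds the dosages of nearby variants (minor allele frequency at least
#' `maf_min`) as covariates and reports the case/control coefficient.
#' Variants failing the frequency threshold, or monomorphic ones, are
#' excluded with a warning.
#'
#' @param y Probe M-values aligned with the design rows.
#' @param design Base design matrix.
#' @param dosages Numeric matrix (samples x SNPs) of allele dosages in
#'   `[0, 2]`, columns named by SNP id, rows aligned with the design.
#' @param maf_min Minor-allele-frequency threshold (default 0.05).
#' @return List as [fit_probe_ols()], plus `snps_used`.
#' @export
snp_adjusted_assoc <- function(y, design, dosages, maf_min = 0.05) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == nrow(design))
  af <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_min & apply(dosages, 2L, function(x) stats::var(x, na.rm = TRUE) > 0)
  if (any(!keep)) {
    warning("excluded SNP(s) below MAF ", maf_min, " or monomorphic: ",
            paste(colnames(dosages)[!keep], collapse = ", "))
  }
  if (!any(keep)) {
    fit <- fit_probe_ols(y, design)
    fit$snps_used <- character()
    return(fit)
  }
  D <- dosages[, keep, drop = FALSE]
  ok <- stats::complete.cases(D) & !is.na(y)
  X <- cbind(design[ok, , drop = FALSE], D[ok, , drop = FALSE])
  fit <- fit_probe_ols(y[ok], X)
  fit$snps_used <- colnames(D)
  fit
}

#' Test whether a SNP is a methylation quantitative trait locus
#'
#' Regresses a probe's M-values on a SNP's allele dosage plus covariates
#' and reports the dosage coefficient with its two-sided p-value.
#'
#' @param y Probe M-values.
#' @param dosage SNP allele dosage in `[0, 2]`.
#' @param covariates Optional covariate matrix (no intercept; one is
#'   added).
#' @return List as [fit_probe_ols()] for the dosage term.
#' @export
meqtl_test <- function(y, dosage, covariates = NULL) {
  if (stats::var(dosage, na.rm = TRUE) == 0) {
    stop("dosage is constant; meQTL test undefined", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit_probe_ols(y, X, coef_name = "dosage")
}

#' Sensitivity report for a set of top probes
#'
#' For each probe: the baseline case/control fit, a refit per extra
#' covariate, a SNP-dosage-adjusted refit using the manifest's nearby
#' variants, and meQTL tests of those variants.
#'
#' @param m Probe-by-sample M-value matrix.
#' @param probes Probe ids to examine.
#' @param design Base design matrix (rows named by sample id).
#' @param phenotypes Phenotype table supplying the extra covariates and
#'   `snp_<id>` dosage columns.
#' @param extra_covariates Phenotype columns to refit with (default
#'   `c("depression", "ssri", "alcohol")`, intersected with what exists).
#' @param manifest Optional manifest with `snps` column for per-probe
#'   nearby variants.
#' @param maf_min MAF threshold for SNP adjustment (default 0.05).
#' @return data.frame with one row per probe/analysis combination:
#'   `probe_id`, `analysis`, `coef`, `se`, `p`, `n`.
#' @export
sensitivity_report <- function(m, probes, design, phenotypes,
                               extra_covariates = c("depression", "ssri", "alcohol"),
                               manifest = NULL, maf_min = 0.05) {
  ph <- phenotypes[match(rownames(design), phenotypes$sample_id), , drop = FALSE]
  extra_covariates <- intersect(extra_covariates, colnames(ph))
  rows <- list()
  for (pid in probes) {
    y <- m[pid, rownames(design)]
    base <- fit_probe_ols(y, design)
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = pid, analysis = "baseline", coef = base$coef, se = base$se,
      p = base$p, n = base$n, stringsAsFactors = FALSE)
    for (cv in extra_covariates) {
      f <- refit_with_covariate(y, design, ph[[cv]], name = cv)
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = pid, analysis = paste0("+", cv), coef = f$coef, se = f$se,
        p = f$p, n = f$n, stringsAsFactors = FALSE)
    }
    if (!is.null(manifest)) {
      snps <- manifest$snps[match(pid, manifest$probe_id)]
      snp_ids <- if (!is.na(snps) && nzchar(snps)) {
        strsplit(snps, ";", fixed = TRUE)[[1L]]
      } else character()
      snp_cols <- paste0("snp_", snp_ids)
      snp_cols <- snp_cols[snp_cols %in% colnames(ph)]
      if (length(snp_cols)) {
        D <- as.matrix(ph[snp_cols])
        f <- snp_adjusted_assoc(y, design, D, maf_min = maf_min)
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = pid, analysis = "+snp_dosage", coef = f$coef, se = f$se,
          p = f$p, n = f$n, stringsAsFactors = FALSE)
        for (sc in snp_cols) {
          mq <- tryCatch(meqtl_test(y, ph[[sc]], design[, -(1:2), drop = FALSE]),
                         error = function(e) NULL)
          if (!is.null(mq)) {
            rows[[length(rows) + 1L]] <- data.frame(
              probe_id = pid, analysis = paste0("meqtl_", sub("^snp_", "", sc)),
              coef = mq$coef, se = mq$se, p = mq$p, n = mq$n,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
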