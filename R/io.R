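#' Read a probe-by-sample beta-value matrix from TSV
#'
#' The file has probe ids in the first column, sample ids in the header row,
#' and beta values in the body. Values outside `[clamp_epsilon,
#' 1 - clamp_epsilon]` are clamped inwards so that the logit transform is
#' defined; the logit is undefined at exactly 0 or 1 and arrays do report
#' such boundary values.
#'
#' @param path Path to a TSV file.
#' @param clamp_epsilon Clamping margin (default 1e-6).
#' @return Numeric matrix (probes x samples) with dimnames; missing cells are
#'   `NA`. The number of clamped and missing cells is attached as attributes
#'   `n_clamped` and `n_missing`.
#' @export
read_beta_matrix <- function(path, clamp_epsilon = 1e-6) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("beta matrix needs a probe-id column and >= 1 sample", call. = FALSE)
  probe_ids <- as.character(df[[1L]])
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe ids in beta matrix: ",
         paste(unique(probe_ids[duplicated(probe_ids)])[1:3], collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in beta matrix", call. = FALSE)
  body <- df[-1L]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric beta value at probe '%s', sample '%s'",
                     probe_ids[bad[1L]], sample_ids[j]), call. = FALSE)
      }
      body[[j]] <- num
    }
  }
  x <- as.matrix(body)
  dimnames(x) <- list(probe_ids, sample_ids)
  out_of_range <- !is.na(x) & (x < 0 | x > 1)
  if (any(out_of_range)) stop("beta values outside [0, 1] in ", path, call. = FALSE)
  n_clamped <- sum(!is.na(x) & (x < clamp_epsilon | x > 1 - clamp_epsilon))
  x[!is.na(x) & x < clamp_epsilon] <- clamp_epsilon
  x[!is.na(x) & x > 1 - clamp_epsilon] <- 1 - clamp_epsilon
  attr(x, "n_clamped") <- n_clamped
  attr(x, "n_missing") <- sum(is.na(x))
  x
}

#' Write a beta-value matrix to TSV
#' @param beta Probe-by-sample numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read a probe manifest CSV
#'
#' Required columns: `probe_id`, `chr`, `pos` (1-based), `gene`
#' (semicolon-separated symbols, empty for intergenic), `on_450k`, `on_epic`
#' (logical/0-1 platform flags). Optional: `snps` (semicolon-separated
#' nearby-SNP ids).
#'
#' @param path Path to the CSV.
#' @return data.frame with one row per probe; `on_450k`/`on_epic` logical.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("probe_id", "chr", "pos", "gene", "on_450k", "on_epic"),
                  "manifest")
  if (anyDuplicated(df$probe_id)) stop("manifest has duplicate probe ids", call. = FALSE)
  if (any(!is.finite(df$pos)) || any(df$pos < 1)) {
    stop("manifest positions must be 1-based integers >= 1", call. = FALSE)
  }
  df$on_450k <- as.logical(df$on_450k)
  df$on_epic <- as.logical(df$on_epic)
  if (any(!df$on_450k & !df$on_epic)) {
    stop("every manifest probe must carry at least one platform flag", call. = FALSE)
  }
  if (is.null(df$snps)) df$snps <- ""
  df$gene[is.na(df$gene)] <- ""
  df
}

#' Read a sample phenotype table CSV
#'
#' Required columns: `sample_id`, `subject_id`, `ptsd`, `age`, `sex`.
#' Ancestry PCs are columns `pc1`, `pc2`, ...; SNP dosages are columns
#' prefixed `snp_`; all other columns pass through.
#'
#' @param path Path to the CSV.
#' @return data.frame with one row per sample.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("sample_id", "subject_id", "ptsd", "age", "sex"),
                  "phenotype table")
  if (anyDuplicated(df$sample_id)) stop("phenotype table has duplicate sample ids", call. = FALSE)
  pcs <- grep("^pc[0-9]+$", colnames(df), value = TRUE)
  if (length(pcs) && any(!is.finite(as.matrix(df[pcs])))) {
    stop("ancestry PCs must be finite", call. = FALSE)
  }
  snps <- grep("^snp_", colnames(df), value = TRUE)
  if (length(snps)) {
    dos <- as.matrix(df[snps])
    if (any(dos < 0 | dos > 2, na.rm = TRUE)) {
      stop("SNP dosages must lie in [0, 2]", call. = FALSE)
    }
  }
  df
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member gene symbols.
#' Symbols are uppercased on load; empty sets are rejected.
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(g) unique(toupper(g[nzchar(g)])))
  if (any(lengths(sets) == 0L)) stop("GMT contains an empty gene set", call. = FALSE)
  sets
}

#' Read a smoking-score probe weight table CSV
#'
#' Columns `probe_id` and `weight`: per-probe effect-size estimates from an
#' external smoking EWAS, used as score weights.
#'
#' @param path Path to the CSV.
#' @return Named numeric vector of weights keyed by probe id.
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("probe_id", "weight"), "weight table")
  if (nrow(df) < 1L) stop("weight table must contain at least one probe", call. = FALSE)
  if (any(!is.finite(df$weight))) stop("weights must be finite", call. = FALSE)
  stats::setNames(df$weight, df$probe_id)
}

#' Write an EWAS result table to TSV, sorted by p-value
#' @param results data.frame with at least columns `probe_id` and `p`.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  require_columns(results, c("probe_id", "p"), "result table")
  results <- results[order(results$p), , drop = FALSE]
  utils::write.table(format(results, digits = 15, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EWAS result table written by [write_results()]
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
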