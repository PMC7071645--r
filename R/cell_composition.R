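#' Estimate cell-type fractions by constrained projection
#'
#' Reference-based deconvolution: for each sample, find the mixture of
#' reference cell-type methylation profiles that best explains its observed
#' beta values, in the least-squares sense, subject to the fractions being
#' nonnegative and summing to one. This is the standard constrained-projection
#' approach used to adjust bulk-tissue association models for cell
#' composition.
#'
#' The simplex-constrained quadratic program is solved exactly: for every
#' support (subset of cell types allowed to be nonzero) the
#' equality-constrained least-squares problem has a closed form via its KKT
#' system, and the feasible solution with the smallest residual is returned.
#' With the handful of cell types found in reference panels this exhaustive
#' search is cheap and has no convergence tolerance.
#'
#' @param beta Probe-by-sample beta matrix; only probes present in the
#'   reference are used.
#' @param ref Probe-by-cell-type matrix of reference mean betas (rownames
#'   are probe ids, colnames cell-type names). Must have full column rank on
#'   the shared probes.
#' @return List with `fractions` (sample-by-cell-type matrix, rows summing
#'   to 1) and `residual` (per-sample residual norm).
#' @export
estimate_fractions <- function(beta, ref) {
  stopifnot(is.matrix(ref), ncol(ref) >= 2L, !is.null(rownames(ref)))
  probes <- intersect(rownames(ref), rownames(beta))
  if (length(probes) < ncol(ref)) {
    stop("need at least as many shared reference probes as cell types", call. = FALSE)
  }
  R <- ref[probes, , drop = FALSE]
  if (qr(R)$rank < ncol(R)) {
    cors <- stats::cor(R)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1L, ]
    stop("reference profiles are rank deficient; near-collinear cell types: ",
         paste(sort(colnames(R)[worst]), collapse = ", "), call. = FALSE)
  }
  B <- beta[probes, , drop = FALSE]
  K <- ncol(R)
  supports <- lapply(seq_len(2^K - 1L), function(mask) which(bitwAnd(mask, 2^(seq_len(K) - 1L)) > 0))
  fractions <- matrix(0, ncol(B), K, dimnames = list(colnames(B), colnames(R)))
  residual <- numeric(ncol(B))
  for (s in seq_len(ncol(B))) {
    y <- B[, s]
    ok <- !is.na(y)
    sol <- simplex_ls(R[ok, , drop = FALSE], y[ok], supports)
    fractions[s, ] <- sol$f
    residual[s] <- sol$resid
  }
  list(fractions = fractions, residual = residual)
}

# Exact minimizer of ||y - R f|| s.t. f >= 0, sum(f) = 1, by support search.
simplex_ls <- function(R, y, supports = NULL) {
  K <- ncol(R)
  if (is.null(supports)) {
    supports <- lapply(seq_len(2^K - 1L), function(mask) which(bitwAnd(mask, 2^(seq_len(K) - 1L)) > 0))
  }
  best <- NULL
  best_rss <- Inf
  for (S in supports) {
    k <- length(S)
    Rs <- R[, S, drop = FALSE]
    # KKT system for min ||y - Rs f||^2 s.t. 1'f = 1
    A <- rbind(cbind(2 * crossprod(Rs), rep(1, k)), c(rep(1, k), 0))
    b <- c(2 * crossprod(Rs, y), 1)
    f_s <- tryCatch(solve(A, b)[seq_len(k)], error = function(e) NULL)
    if (is.null(f_s) || any(f_s < -1e-10)) next
    f <- numeric(K)
    f[S] <- pmax(f_s, 0)
    f <- f / sum(f)
    rss <- sum((y - R %*% f)^2)
    if (rss < best_rss - 1e-15) {
      best_rss <- rss
      best <- f
    }
  }
  list(f = best, resid = sqrt(best_rss))
}

#' Estimate the neuronal proportion of brain samples
#'
#' Two-component (neuron/glia) special case of [estimate_fractions()];
#' returns the neuron coordinate per sample.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param ref Reference matrix whose columns include `neuron` and `glia`.
#' @return Named numeric vector of neuron fractions in `[0, 1]`.
#' @export
estimate_neuron_fraction <- function(beta, ref) {
  if (!all(c("neuron", "glia") %in% colnames(ref))) {
    stop("reference must contain 'neuron' and 'glia' columns", call. = FALSE)
  }
  est <- estimate_fractions(beta, ref[, c("neuron", "glia")])
  est$fractions[, "neuron"]
}
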