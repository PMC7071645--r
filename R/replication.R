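#' Find a cross-platform proxy probe for a peak locus
#'
#' Replication cohorts assayed on the 450K chip cannot be queried for
#' EPIC-only peak probes directly. A proxy is a probe present on both
#' platforms, on the same chromosome within `window` bp of the peak, whose
#' beta values are positively and significantly (Pearson p < `alpha`)
#' correlated with the peak's. Among eligible candidates the one with the
#' largest correlation is chosen; ties are broken by probe id. A peak that is
#' itself on both platforms is its own proxy at distance 0.
#'
#' @param peak Probe id of the peak locus.
#' @param manifest Probe manifest (see [read_manifest()]).
#' @param beta Probe-by-sample beta matrix used to compute correlations
#'   (normally the discovery cohort's).
#' @param window Maximum distance in bp (default 5000).
#' @param alpha Correlation significance threshold (default 0.05).
#' @return List (`ProxyAssignment`): `peak`, `proxy` (id or `NA`),
#'   `distance`, `r`, `r_p`.
#' @export
find_proxy <- function(peak, manifest, beta, window = 5000, alpha = 0.05) {
  i <- match(peak, manifest$probe_id)
  if (is.na(i)) stop("peak probe absent from manifest: ", peak, call. = FALSE)
  if (!peak %in% rownames(beta)) stop("peak probe absent from beta matrix: ", peak, call. = FALSE)
  if (isTRUE(manifest$on_450k[i]) && isTRUE(manifest$on_epic[i])) {
    return(list(peak = peak, proxy = peak, distance = 0, r = 1, r_p = 0))
  }
  cand <- manifest[manifest$chr == manifest$chr[i] &
                     abs(manifest$pos - manifest$pos[i]) <= window &
                     manifest$on_450k & manifest$on_epic &
                     manifest$probe_id != peak, , drop = FALSE]
  cand <- cand[cand$probe_id %in% rownames(beta), , drop = FALSE]
  none <- list(peak = peak, proxy = NA_character_, distance = NA_real_,
               r = NA_real_, r_p = NA_real_)
  if (nrow(cand) == 0L) return(none)
  y <- beta[peak, ]
  best <- none
  for (k in order(cand$probe_id)) {
    x <- beta[cand$probe_id[k], ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) next
    ct <- stats::cor.test(x[ok], y[ok])
    if (is.na(ct$estimate) || ct$estimate <= 0 || ct$p.value >= alpha) next
    if (is.na(best$r) || ct$estimate > best$r) {
      best <- list(peak = peak, proxy = cand$probe_id[k],
                   distance = abs(cand$pos[k] - manifest$pos[i]),
                   r = unname(ct$estimate), r_p = ct$p.value)
    }
  }
  best
}

#' Exact binomial test for an excess of nominally significant loci
#'
#' Upper-tail probability \eqn{P(X \ge k)} with
#' \eqn{X \sim \mathrm{Binomial}(n, \alpha)}: the chance of observing at
#' least the seen number of nominally significant replication results if
#' each of the examined loci had an `alpha` chance of nominal significance
#' under the null.
#'
#' @param n_nominal Observed count of nominally significant loci.
#' @param n_tested Number of loci examined.
#' @param alpha Per-locus null success probability (default 0.05).
#' @return P-value.
#' @export
#' @examples
#' excess_significance_test(8, 60) # 0.0098
excess_significance_test <- function(n_nominal, n_tested, alpha = 0.05) {
  assert_count(n_nominal, "n_nominal")
  assert_count(n_tested, "n_tested")
  if (n_nominal > n_tested) stop("n_nominal cannot exceed n_tested", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (n_nominal == 0L) return(1)
  stats::pbinom(n_nominal - 1L, n_tested, alpha, lower.tail = FALSE)
}

#' Two-sided exact sign test for direction-of-effect agreement
#'
#' Tests the number of loci whose effect direction agrees between two
#' cohorts against a 50% null: twice the smaller binomial tail at success
#' probability 0.5, capped at 1.
#'
#' @param n_agree Number of agreeing loci.
#' @param n_total Number of loci compared.
#' @return Two-sided p-value.
#' @export
#' @examples
#' sign_agreement_test(14, 14) # 2 * 0.5^14 = 0.00012
sign_agreement_test <- function(n_agree, n_total) {
  assert_count(n_agree, "n_agree")
  assert_count(n_total, "n_total")
  if (n_agree > n_total) stop("n_agree cannot exceed n_total", call. = FALSE)
  lower <- stats::pbinom(n_agree, n_total, 0.5)
  upper <- stats::pbinom(n_agree - 1L, n_total, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Correlation of effect sizes between cohorts, overall and by strata
#'
#' Pearson correlation of discovery and replication coefficients across
#' shared loci, reported for all loci and for the subsets with replication
#' p below each threshold. Strata with fewer than 3 loci are reported as
#' not computable (`NA`) rather than raising an error.
#'
#' @param disc_coef,repl_coef Paired coefficient vectors.
#' @param repl_p Replication p-values defining the strata.
#' @param thresholds Stratum thresholds (default `c(0.10, 0.05)`).
#' @return data.frame: `stratum`, `n`, `r`, `p`.
#' @export
effect_correlation <- function(disc_coef, repl_coef, repl_p,
                               thresholds = c(0.10, 0.05)) {
  stopifnot(length(disc_coef) == length(repl_coef),
            length(repl_coef) == length(repl_p))
  one <- function(idx, label) {
    if (sum(idx, na.rm = TRUE) < 3L) {
      return(data.frame(stratum = label, n = sum(idx, na.rm = TRUE),
                        r = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(disc_coef[idx], repl_coef[idx])
    data.frame(stratum = label, n = sum(idx), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }
  ok <- !is.na(disc_coef) & !is.na(repl_coef) & !is.na(repl_p)
  out <- one(ok, "all")
  for (th in thresholds) {
    out <- rbind(out, one(ok & repl_p < th, sprintf("p<%g", th)))
  }
  rownames(out) <- NULL
  out
}

#' Replicate the top discovery loci in a second cohort
#'
#' Selects the top `k` discovery probes by p-value, maps each to itself or a
#' cross-platform proxy ([find_proxy()]), and summarizes the evidence for
#' replication: the count of nominally significant replication results with
#' its exact binomial p ([excess_significance_test()]), direction-of-effect
#' agreement among loci with replication p < `direction_threshold` with its
#' exact sign-test p ([sign_agreement_test()]), effect-size correlations by
#' strata ([effect_correlation()]), and per-locus Benjamini-Hochberg
#' adjusted replication p-values with `m_total` equal to the number of loci
#' actually examined.
#'
#' @param discovery Discovery `EwasResultTable`.
#' @param replication Replication `EwasResultTable` (450K results).
#' @param manifest Probe manifest shared by both cohorts.
#' @param beta_for_proxy Beta matrix used for proxy correlations.
#' @param k Number of top discovery loci (default 100).
#' @param alpha Nominal significance level (default 0.05).
#' @param direction_threshold Replication-p cutoff for the sign test
#'   (default 0.10).
#' @param proxy_window Proxy search window in bp (default 5000).
#' @return List (`ReplicationReport`): `n_examined`, `n_nominal`,
#'   `excess_p`, `n_direction`, `n_agree`, `sign_p`, `correlations`,
#'   and `loci` (per-locus data.frame with `p_adj` over the examined loci).
#' @export
replicate_top_loci <- function(discovery, replication, manifest,
                               beta_for_proxy, k = 100, alpha = 0.05,
                               direction_threshold = 0.10,
                               proxy_window = 5000) {
  top <- utils::head(discovery[order(discovery$p, -abs(discovery$coef),
                                     discovery$probe_id), ], k)
  rows <- lapply(top$probe_id, function(pid) {
    pr <- find_proxy(pid, manifest, beta_for_proxy, window = proxy_window)
    j <- if (!is.na(pr$proxy)) match(pr$proxy, replication$probe_id) else NA_integer_
    data.frame(
      peak = pid,
      proxy = pr$proxy,
      is_proxy = !is.na(pr$proxy) && pr$proxy != pid,
      disc_coef = top$coef[match(pid, top$probe_id)],
      disc_p = top$p[match(pid, top$probe_id)],
      repl_coef = if (!is.na(j)) replication$coef[j] else NA_real_,
      repl_p = if (!is.na(j)) replication$p[j] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  loci <- do.call(rbind, rows)
  examined <- loci[!is.na(loci$repl_p), , drop = FALSE]
  if (nrow(examined) == 0L) stop("no top loci mappable into the replication results", call. = FALSE)
  examined$p_adj <- bh_adjust(examined$repl_p, m_total = nrow(examined))
  n_nominal <- sum(examined$repl_p < alpha)
  dir_idx <- examined$repl_p < direction_threshold
  n_agree <- sum(sign(examined$disc_coef[dir_idx]) == sign(examined$repl_coef[dir_idx]))
  list(
    n_examined = nrow(examined),
    n_nominal = n_nominal,
    excess_p = excess_significance_test(n_nominal, nrow(examined), alpha),
    n_direction = sum(dir_idx),
    n_agree = n_agree,
    sign_p = if (sum(dir_idx) > 0) sign_agreement_test(n_agree, sum(dir_idx)) else NA_real_,
    correlations = effect_correlation(examined$disc_coef, examined$repl_coef,
                                      examined$repl_p,
                                      thresholds = c(direction_threshold, alpha)),
    loci = examined[order(examined$repl_p), , drop = FALSE]
  )
}

#' Candidate-probe analysis with FDR over the candidate list
#'
#' Looks up previously implicated CpG sites in a result table (which may
#' include low-variation probes retained for this purpose) and
#' Benjamini-Hochberg-adjusts their p-values with `m_total` equal to the
#' number of candidates. Absent candidates are listed as missing, not fatal.
#'
#' @param results `EwasResultTable` including retained filtered probes.
#' @param candidates Character vector of candidate probe ids.
#' @return List: `table` (candidates found, with `p_adj`), `missing`
#'   (candidate ids absent from the results).
#' @export
candidate_probe_analysis <- function(results, candidates) {
  if (length(candidates) < 1L) stop("need at least one candidate probe", call. = FALSE)
  idx <- match(candidates, results$probe_id)
  found <- results[idx[!is.na(idx)], c("probe_id", "gene", "coef", "p"), drop = FALSE]
  if (nrow(found)) {
    found$p_adj <- bh_adjust(found$p, m_total = length(candidates))
    found <- found[order(found$p), , drop = FALSE]
    rownames(found) <- NULL
  }
  list(table = found, missing = candidates[is.na(idx)])
}

#' Candidate-gene analysis with gene-wide FDR
#'
#' For each candidate gene, adjusts the p-values of all its probes by
#' Benjamini-Hochberg with `m_total` equal to that gene's probe count, and
#' reports the best (minimum adjusted p) probe per gene.
#'
#' @param results `EwasResultTable`.
#' @param genes Character vector of gene symbols.
#' @param manifest Probe manifest mapping probes to genes.
#' @return data.frame: `gene`, `n_probes`, `best_probe`, `coef`, `p`,
#'   `p_adj`; genes without probes get `n_probes = 0` and `NA` statistics.
#' @export
candidate_gene_analysis <- function(results, genes, manifest) {
  probe_genes <- strsplit(manifest$gene, ";", fixed = TRUE)
  rows <- lapply(genes, function(g) {
    pids <- manifest$probe_id[vapply(probe_genes, function(x) g %in% x, logical(1))]
    sub <- results[results$probe_id %in% pids, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(gene = g, n_probes = 0L, best_probe = NA_character_,
                        coef = NA_real_, p = NA_real_, p_adj = NA_real_,
                        stringsAsFactors = FALSE))
    }
    padj <- bh_adjust(sub$p, m_total = nrow(sub))
    best <- order(padj, sub$p, sub$probe_id)[1L]
    data.frame(gene = g, n_probes = nrow(sub), best_probe = sub$probe_id[best],
               coef = sub$coef[best], p = sub$p[best], p_adj = padj[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
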