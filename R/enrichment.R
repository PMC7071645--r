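# Probe-count-bias-corrected gene-set enrichment of top EWAS loci.
#
# Genes covered by many CpG probes are more likely to contribute a probe to
# any top-k list, significant or not. Enrichment therefore models gene
# selection as biased sampling without replacement, with per-gene odds
# estimated from the observed relationship between probe count and
# selection probability (a probability-weighting function), and the set
# test uses the Wallenius noncentral hypergeometric tail instead of the
# ordinary (Fisher) hypergeometric.

#' Derive significant and universe gene lists from top-k probes
#'
#' The significant genes are the unique gene symbols of the `k` smallest-p
#' probes (intergenic probes are dropped); the universe is every gene with
#' at least one analyzed probe; per-gene probe counts come from the
#' analyzed probes.
#'
#' @param results `EwasResultTable` of analyzed probes.
#' @param manifest Probe manifest (genes semicolon-separated; a probe
#'   contributes to every listed gene).
#' @param k Number of top probes (default 500).
#' @return List: `significant` (character), `universe` (character),
#'   `probes_per_gene` (named integer vector over the universe).
#' @export
top_k_gene_list <- function(results, manifest, k = 500) {
  if (k > nrow(results)) stop("k exceeds the number of result rows", call. = FALSE)
  genes_of <- function(probe_ids) {
    g <- manifest$gene[match(probe_ids, manifest$probe_id)]
    g <- unlist(strsplit(g[!is.na(g) & nzchar(g)], ";", fixed = TRUE))
    unique(toupper(g[nzchar(g)]))
  }
  ord <- order(results$p, -abs(results$coef), results$probe_id)
  sig <- genes_of(results$probe_id[ord][seq_len(k)])
  all_genes <- manifest$gene[match(results$probe_id, manifest$probe_id)]
  gene_lists <- strsplit(ifelse(is.na(all_genes), "", all_genes), ";", fixed = TRUE)
  flat <- toupper(unlist(gene_lists))
  flat <- flat[nzchar(flat)]
  counts <- table(flat)
  universe <- names(counts)
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  list(significant = intersect(sig, universe), universe = universe,
       probes_per_gene = stats::setNames(as.integer(counts), universe))
}

#' Estimate per-gene selection odds from probe-count bias
#'
#' Fits a monotone (isotonic) estimate of the probability that a gene is
#' selected as significant given its probe count, then converts the fitted
#' probabilities to odds and normalizes them to mean 1. When all genes have
#' the same probe count, or no gene is significant, the odds are uniform.
#'
#' @param probes_per_gene Named integer vector (gene -> probe count).
#' @param significant Character vector of significant genes.
#' @return Named numeric vector of selection odds, mean 1.
#' @export
probe_bias_weights <- function(probes_per_gene, significant) {
  genes <- names(probes_per_gene)
  y <- as.numeric(genes %in% significant)
  uniform <- stats::setNames(rep(1, length(genes)), genes)
  if (length(unique(probes_per_gene)) < 2L) return(uniform)
  if (sum(y) == 0L) {
    warning("no significant genes; returning uniform selection odds")
    return(uniform)
  }
  iso <- stats::isoreg(probes_per_gene, y)
  # isoreg sorts by x; map fitted values back to input order
  fit <- numeric(length(genes))
  fit[iso$ord] <- iso$yf
  eps <- 1e-4
  fit <- pmin(pmax(fit, eps), 1 - eps)
  odds <- fit / (1 - fit)
  odds <- odds / mean(odds)
  stats::setNames(odds, genes)
}

# Exact Wallenius noncentral hypergeometric upper tail by dynamic
# programming over sequential biased draws without replacement:
# P(draw from group 1 | x drawn from group 1, y from group 2)
#   = w1 (m1 - x) / (w1 (m1 - x) + w2 (m2 - y)).
wallenius_upper_tail <- function(x_obs, m1, m2, n, w1, w2) {
  if (n > m1 + m2) stop("cannot draw more than the universe size", call. = FALSE)
  if (x_obs <= max(0L, n - m2)) return(1)
  # prob[x + 1] = P(X = x) after t draws
  prob <- c(1, rep(0, n))
  for (t in seq_len(n)) {
    new <- rep(0, n + 1L)
    for (x in 0:(t - 1L)) {
      p_x <- prob[x + 1L]
      if (p_x == 0) next
      y <- t - 1L - x
      a <- w1 * (m1 - x)
      b <- w2 * (m2 - y)
      if (a < 0 || b < 0) next
      tot <- a + b
      if (tot <= 0) next
      new[x + 2L] <- new[x + 2L] + p_x * a / tot
      new[x + 1L] <- new[x + 1L] + p_x * b / tot
    }
    prob <- new
  }
  sum(prob[(x_obs + 1L):(n + 1L)])
}

#' Wallenius noncentral hypergeometric set test
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' gene set and the significant genes, under biased sampling without
#' replacement in which set members are drawn with the set's mean odds and
#' the remaining universe with the complementary mean odds (the practical
#' two-group approximation). With all odds equal the test reduces exactly
#' to the hypergeometric (Fisher) upper tail. The tail is computed by exact
#' dynamic programming over the sequential draws.
#'
#' @param set_genes Gene symbols in the set.
#' @param universe All measured genes.
#' @param significant Significant genes (subset of universe).
#' @param odds Named per-gene odds (default uniform).
#' @return List: `p`, `n_set` (set genes in universe), `n_overlap`
#'   (significant set genes), `disjoint` flag (p = 1 when the set does not
#'   intersect the universe).
#' @export
wallenius_set_test <- function(set_genes, universe, significant, odds = NULL) {
  set_genes <- intersect(set_genes, universe)
  m1 <- length(set_genes)
  if (m1 == 0L) {
    return(list(p = 1, n_set = 0L, n_overlap = 0L, disjoint = TRUE))
  }
  if (is.null(odds)) odds <- stats::setNames(rep(1, length(universe)), universe)
  m2 <- length(universe) - m1
  n <- length(intersect(significant, universe))
  x_obs <- length(intersect(set_genes, significant))
  w1 <- mean(odds[set_genes])
  w2 <- if (m2 > 0) mean(odds[setdiff(universe, set_genes)]) else 1
  p <- if (m2 == 0L) 1 else wallenius_upper_tail(x_obs, m1, m2, n, w1, w2)
  list(p = min(max(p, .Machine$double.xmin), 1), n_set = m1,
       n_overlap = x_obs, disjoint = FALSE)
}

#' Run probe-bias-corrected gene-set enrichment
#'
#' Composes [top_k_gene_list()], [probe_bias_weights()] and
#' [wallenius_set_test()] over a gene-set collection and adjusts the set
#' p-values by Benjamini-Hochberg with `m_total` equal to the number of
#' sets tested.
#'
#' @param results `EwasResultTable` of analyzed probes.
#' @param manifest Probe manifest.
#' @param gene_sets Named list of gene symbol vectors (see [read_gmt()]).
#' @param k Number of top probes defining the significant genes
#'   (default 500).
#' @return data.frame (`EnrichmentResult`): `set`, `n_genes`, `n_de`, `p`,
#'   `p_adj`, `genes` (contributing significant genes, semicolon-joined),
#'   sorted by p.
#' @export
run_enrichment <- function(results, manifest, gene_sets, k = 500) {
  lists <- top_k_gene_list(results, manifest, k = k)
  odds <- probe_bias_weights(lists$probes_per_gene, lists$significant)
  rows <- lapply(names(gene_sets), function(nm) {
    tst <- wallenius_set_test(gene_sets[[nm]], lists$universe,
                              lists$significant, odds)
    contributing <- intersect(intersect(gene_sets[[nm]], lists$universe),
                              lists$significant)
    data.frame(set = nm, n_genes = tst$n_set, n_de = tst$n_overlap,
               p = tst$p, genes = paste(sort(contributing), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p, m_total = nrow(out))
  out <- out[order(out$p, out$set), c("set", "n_genes", "n_de", "p", "p_adj", "genes")]
  rownames(out) <- NULL
  out
}
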