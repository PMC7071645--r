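# Shared fixtures, built once per run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# A small but fully featured cohort configuration used across files.
tiny_config <- function(...) {
  args <- list(n_probes = 600, n_cases = 60, n_controls = 40,
               n_causal_probes = 15, n_smoking_probes = 10, n_snps = 5,
               n_pcs = 2, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

tiny_blood <- function() fixture("tiny_blood", simulate_blood_cohort(tiny_config()))

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p, m_total = length(p)) {
  ord <- order(p)
  k <- length(p)
  q <- numeric(k)
  for (i in seq_len(k)) {
    q[ord[i]] <- min(1, min(p[ord][i:k] * m_total / (i:k)))
  }
  q
}

# Exact binomial tail by direct pmf summation.
binom_tail_oracle <- function(k, n, prob) {
  sum(vapply(k:n, function(x) choose(n, x) * prob^x * (1 - prob)^(n - x),
             numeric(1)))
}
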