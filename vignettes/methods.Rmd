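---
title: "Methods: a blood-and-brain EWAS of PTSD on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a blood-and-brain EWAS of PTSD on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`methewas` implements an epigenome-wide association study (EWAS) of
post-traumatic stress disorder across whole blood and postmortem prefrontal
cortex, as a chain of testable stages. The response throughout is the
M-value, the base-2 logit of the methylated proportion
$M = \log_2\!\big(\beta/(1-\beta)\big)$, on which per-probe linear models
are closer to homoscedastic and additive than on the bounded beta scale.

The discovery model for probe $j$ and sample $s$ is

$$ M_{js} = \alpha_j + \gamma_j\,\mathrm{PTSD}_s + \mathbf{x}_s^\top
\boldsymbol\delta_j + \varepsilon_{js}, $$

where $\mathbf{x}_s$ stacks ancestry principal components, age, sex,
estimated white-blood-cell fractions (one type dropped; see below) and a
DNA-methylation smoking score. Interest is in $\gamma_j$, the case minus
control difference on the M scale.

# Stage-by-stage choices

## Probe filtering

Probes whose beta-value **range** across samples is below 0.10 are excluded
before the EWAS: such probes sit near full methylation or full
unmethylation, where array noise dominates and cross-platform replication
is unreliable. Two deliberate readings: the range is computed on the beta
scale (the scale the criterion is stated on, not the M scale), and the
exclusion is strictly `< 0.10`, so a range of exactly 0.10 is retained (a
`1e-12` guard absorbs floating-point rounding at the boundary). The range
is taken over all subjects jointly, not within groups. Filtered probes are
still fit and kept in a side table, because previously reported candidate
probes must be looked up even when low-varying.

## Cell composition

Bulk methylation mixes cell types, and cell composition differs by
diagnosis and stress exposure, so per-sample fractions are estimated and
adjusted for. Estimation is reference-based constrained projection: the
sample's beta vector over reference probes is approximated by a convex
combination of cell-type mean profiles, minimizing squared error subject
to nonnegativity and sum-to-one. With the small number of cell types in a
reference panel the simplex-constrained least-squares problem is solved
*exactly* by enumerating supports and solving each equality-constrained
subproblem via its KKT system — no iterative tolerance. Sum-to-one is
enforced exactly; because the fractions then live on a simplex, the
largest-mean cell type is dropped from the design matrix to avoid exact
collinearity with the intercept. Brain samples use the two-type
(neuron/glia) special case and only the neuron coordinate enters the model.

## Smoking score

The score is $\mathrm{score}_s = \sum_j w_j M_{js}$ over an externally
estimated probe-weight table (canonically the top 39 smoking-associated
probes, led by the *AHRR* probe cg05575921), z-standardized across samples
before entering the design. Whether the original score was computed on the
beta or M scale is not recoverable from the published description; the M
scale is the default here because it matches the regression scale of the
source effect estimates, and the choice is configurable in the sense that
the score is a plain weighted sum of whatever matrix is supplied. Weight
probes absent from a platform subset are skipped with a warning rather
than imputed, so the score stays defined on 450K-only data. A `leave_out`
argument supports the sensitivity analysis in which a probe of interest is
removed from its own covariate.

## Per-probe models and moderation

Each probe is fit by ordinary least squares against the shared design
(QR-factorized once for all probes). Residual variances are then shrunk by
empirical Bayes: a scaled inverse-chi-square prior with degrees of freedom
$d_0$ and scale $s_0^2$ is fit to the ensemble of variances by the method
of moments on log variances — the spread of $\log s^2$ beyond what
$\psi'(d/2)$ explains identifies $\psi'(d_0/2)$, inverted by Newton
iteration — and the posterior variance
$\tilde s_j^2 = (d_0 s_0^2 + d s_j^2)/(d_0 + d)$ yields a moderated
t-statistic on $d_0 + d$ degrees of freedom. When the variances are no
more dispersed than sampling alone predicts, $d_0 = \infty$ and every
posterior variance equals the ensemble mean. The implementation is
validated in the tests against the canonical microarray implementation of
the same moments method, and by parameter recovery from simulated variance
ensembles. Moderated p-values are the default; unmoderated ones are
available (`moderate = FALSE`) since pipeline defaults of the original
analysis cannot be determined.

## Multiple testing

"Q-values" here are Benjamini–Hochberg step-up adjusted p-values,
$q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, with an **explicit** total test
count `m_total` that may exceed the number of p-values supplied. That
explicit count is what lets the published tables be reproduced from their
printed subsets: the discovery table adjusts 10 printed p-values against
m = 402,607 analyzed probes, the replication table against the 60 loci
examined, the brain table against 100, and the candidate-probe analysis
against 51 candidates. The identity of every printed adjusted p-value
under these counts is what fixes the interpretation of "Q-value" as BH.

## Replication

Cross-platform replication needs a mapping from EPIC-only peaks into 450K
results: a *proxy* is a both-platform probe on the same chromosome within
5,000 bp whose betas correlate with the peak's at p < 0.05; among eligible
candidates the largest positive correlation wins, with probe-id order as
the deterministic tie-break. Only positive correlations are eligible, so
effect directions transfer without sign flips — the published comparison
never sign-flips, and admitting negative proxies would make direction
agreement ill-defined. The report then combines: (a) the count of
nominally significant replication results against an exact upper-tail
binomial $P(X \ge k),\,X\sim\mathrm{Bin}(n, 0.05)$; (b) direction
agreement among loci with replication p < 0.10 against an exact two-sided
sign test (twice the smaller tail at 0.5, capped at 1 — the two-sided
reading is fixed by the printed p = 0.00012 for 14/14, which equals
$2 \times 0.5^{14}$, where a one-sided test would give half that); and
(c) Pearson correlations of effect sizes overall and in the p < 0.10 and
p < 0.05 strata, with strata smaller than 3 reported as not computable.
The candidate-probe count is a parameter: the published Methods and
Results disagree (41 vs 51), and the printed adjusted value 0.00047 is
arithmetically consistent only with 51, so 51 is the default in the
reproduction scripts.

## Paired brain model

Each donor contributes dlPFC and vmPFC samples, so per-probe models use a
subject-level random intercept:
$y = X\boldsymbol\beta + b_{\mathrm{subject}} + e$, with
$b \sim N(0, \sigma_b^2)$, $e \sim N(0, \sigma_e^2)$. With
$\lambda = \sigma_b^2/\sigma_e^2$ the covariance of a donor's block is
$\sigma_e^2(I + \lambda J)$, whose inverse square root is closed-form, so
the REML criterion is profiled down to a one-dimensional search over
$\log\lambda$ (with the $\lambda = 0$ boundary checked explicitly;
non-convergence is flagged, never thrown). Fixed effects come from
generalized least squares at the optimum. The test for the PTSD
coefficient is a Wald t on $n - p - q + 1$ degrees of freedom
(observations minus fixed-effect columns minus subjects plus one) — the
published analysis does not state its df method, and this conservative
fixed-df choice avoids per-probe Satterthwaite machinery while remaining
exact in the balanced two-observation case. Tests validate the fit against
an independent mixed-model implementation and a grid-search oracle over
the variance ratio. The smoking covariate in brain is the binary
history flag, not the DNAm score, which does not track smoking in cortex.

## Enrichment

Genes covered by more probes are more likely to appear in any top-k list,
so set enrichment models gene selection as biased sampling without
replacement. The probability of selection given probe count is estimated
by isotonic regression (a monotone probability-weighting function — the
original tool's internal estimator is not published, and the isotonic fit
is this package's documented stand-in with the same monotone contract),
converted to per-gene odds normalized to mean 1. Each set is tested with
the Wallenius noncentral hypergeometric upper tail, using the set's mean
odds versus the complement's (the standard two-group approximation). The
tail is computed by an exact dynamic program over sequential draws —
$O(n^2)$ in the number of significant genes, exact at every instance size
used here, which is why no separate numerical-integration branch exists.
With all odds equal the DP reduces to the Fisher exact upper tail, an
identity the tests check against `phyper` and, under biased odds, against
Monte-Carlo sampling.

## Sensitivity

Top loci are refit with each extra covariate (depression, SSRI use,
alcohol), with nearby SNP dosages (minor allele frequency ≥ 5%;
monomorphic or rare variants are excluded with a warning), and each
variant is tested directly as an meQTL. Refits are complete-case within
each analysis and report the sample count used, so coefficient
comparisons across refits are auditable. Adding a covariate orthogonal to
the outcome and design leaves the PTSD coefficient exactly unchanged — a
property the tests assert to 1e-8.

# The synthetic cohorts

No individual-level data from the emulated study are distributable, so the
generators are first-class, tested code that defines the study conditions:

* **Sizes.** 378 cases / 135 controls in blood; an independent replication
  cohort of the same size restricted to probes flagged on the 450K
  platform (54% of probes, matching the fraction of top loci that were
  assessable); 42 case and 30 control brain donors with two regions each.
* **Scale.** Generation happens on the M scale — baseline + cell-mixture
  term + PC/age/sex terms + case effect + smoking effect + meQTL dosage
  effect + Gaussian residual — then inverse-logit to beta, so ground-truth
  effects are exact on the scale the models use. The default probe count
  is 4,000 (the analysis suite and drivers are exercised at
  hundreds-to-thousands of probes; the real arrays' ~820,000 probes add
  nothing statistically to per-probe models beyond runtime).
* **Effects.** Spiked case effects default to 0.3 M — the midpoint of the
  0.11–0.53 magnitude range of published top blood loci; this is
  illustrative, not calibrated, as no effect-size distribution for true
  loci is published. Smoking effects default to −1 M (hypomethylation)
  with per-probe variation, at 39 score probes; smoking prevalence is 50%
  in cases vs 30% in controls, deliberately confounding smoking with
  diagnosis. Residual sd defaults to 1 M.
* **Proxies.** Each causal probe gets a designated neighbor 0.8–2 kb away,
  always flagged on both platforms, whose M-values mix in 75% of the
  causal probe's full signal — so the neighbor inherits correlated
  baselines *and* an attenuated case effect, and the proxy search has
  something real to find.
* **Low-variation probes.** A configurable fraction (default 30%) of
  probes sits near the beta boundaries with shrunken residual scale, so
  the range filter removes a known, controllable share.
* **Brain pairing.** Subject intercept variance is `brain_icc` of the
  total residual variance (default 0.6), giving the configured
  within-subject correlation at null probes. Neuron fractions are
  Beta(8, 12) per donor; the neuron/glia contrast is drawn wide, matching
  the unusually strong separation of neuronal methylation. Smoking
  affects blood methylation only — cortical smoking effects are omitted,
  consistent with their reported weakness — while the brain phenotype
  still records smoking history for adjustment.
* **Genetics.** SNP dosages are Binomial(2, MAF) with MAF uniform on
  (0.05, 0.5); each variant targets one probe with a per-allele M effect.
* **Determinism.** All generators restore the caller's RNG state and are
  bit-identical under a fixed seed; blood, replication and brain cohorts
  derive probe identity from a shared seed-determined structure so
  discovery loci exist in the brain matrix.

What the generator does **not** emulate: array-level artifacts (probe
cross-reactivity, batch and chip effects), realistic linkage
disequilibrium, genomic autocorrelation of methylation beyond the
constructed proxy neighbors, and non-Gaussian residuals. Passing tests on
these cohorts therefore demonstrate the correctness and calibration of the
statistical machinery under the declared generative model, not robustness
to real-array pathology.

# Numerical notes

* Beta values are clamped to $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-6}$, on load: the logit is undefined at 0/1 and
  arrays do report boundary values; no handling rule is published, so the
  clamp is explicit and counted.
* Ranking ties for top-k lists break by ascending p, then descending
  |coefficient|, then probe id — determinism over elegance.
* BH inputs must lie in (0, 1]; computed p-values are floored at the
  smallest positive double rather than 0.
* The deconvolution support search prefers a strictly smaller residual
  (by more than 1e-15) so ties resolve to the first, lower-cardinality
  support.
* Mixed-model profiling searches $\log\lambda \in [-12, 12]$ and compares
  the boundary $\lambda = 0$ explicitly; `converged = FALSE` marks fits at
  the upper bound.

# Problem sizes used by the shipped analyses

The numbered drivers under `analysis/` run the default configuration
(4,000 probes, 513 + 513 + 144 samples) end-to-end in well under a minute.
The test suite uses cohorts of 500–4,000 probes, 20 replicates for the
precision and recovery suites, 50,000 simulated variances for the
moderation-recovery check, and 200,000 Monte-Carlo draws for the Wallenius
cross-check. These sizes were chosen so each suite establishes its
property with comfortable sampling margin while the whole suite stays
fast enough to run habitually.

# Known limitations

* The replication cohort reuses the discovery group sizes rather than the
  consortium's n = 1351; power comparisons across cohorts are therefore
  not emulated.
* The smoking score's original scale (beta vs M) and any weight rescaling
  are unknown; only the M-scale weighted sum is implemented.
* The enrichment bias model estimates a single monotone selection curve;
  it does not model per-probe (as opposed to per-gene) selection, gene
  length, or ontology structure — gene sets are flat lists.
* Realized false-discovery proportions in any single simulated EWAS vary
  around the nominal FDR; the precision guarantees in the tests are
  statements about pooled replicates.
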