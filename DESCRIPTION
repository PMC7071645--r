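Package: methewas
Title: Blood and Brain Epigenome-Wide Association Analysis of PTSD with
    Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a blood- and brain-based
    epigenome-wide association study (EWAS) of post-traumatic stress
    disorder: probe variation filtering, reference-based cell-type
    deconvolution, a DNA-methylation smoking score, per-probe
    empirical-Bayes moderated linear models with Benjamini-Hochberg
    false discovery rate control, cross-platform proxy-probe
    replication statistics, a paired brain-region random-intercept
    mixed model, and probe-count-bias-corrected gene-set enrichment.
    Includes synthetic-cohort generators that emulate the study design
    so every stage is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
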