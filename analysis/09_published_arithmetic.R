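#!/usr/bin/env Rscript
# Stage 9: reproduce the published multiple-testing and replication-test
# arithmetic from the reported summary tables shipped with the package:
# BH over the printed p-values at the analysis-wide test counts, and the
# exact binomial tests behind the replication summary.

source("analysis/_common.R")

ext <- function(f) system.file("extdata", f, package = "methewas")

disc <- read.csv(ext("discovery_top10.csv"))
disc$p_adj <- bh_adjust(disc$p, m_total = 402607)
cat("discovery top 10 (BH over m = 402,607):\n")
print(disc, digits = 3)

repl <- read.csv(ext("replication_top5.csv"))
repl$p_adj <- bh_adjust(repl$repl_p, m_total = 60)
cat("\nreplicated loci (BH over the 60 examined):\n")
print(repl[c("gene", "probe_id", "repl_p", "p_adj")], digits = 3)

cat(sprintf("\nexcess significance, 8 of 60 at alpha 0.05: p = %.4f\n",
            excess_significance_test(8, 60, 0.05)))
cat(sprintf("direction agreement, 14 of 14: p = %.5f\n",
            sign_agreement_test(14, 14)))

brain <- read.csv(ext("brain_top6.csv"))
brain$p_adj <- bh_adjust(brain$brain_p, m_total = 100)
cat("\nbrain refits (BH over the 100 examined):\n")
print(brain[c("gene", "probe_id", "brain_p", "p_adj")], digits = 3)

cand <- read.csv(ext("candidate_probes.csv"))
cand$p_adj <- bh_adjust(cand$p, m_total = 51)
cat("\ncandidate probes (BH over the 51 prior loci):\n")
print(cand, digits = 3)

out <- rbind(
  data.frame(table = "discovery", gene = disc$gene, probe_id = disc$probe_id,
             p = disc$p, p_adj = disc$p_adj),
  data.frame(table = "replication", gene = repl$gene, probe_id = repl$probe_id,
             p = repl$repl_p, p_adj = repl$p_adj),
  data.frame(table = "brain", gene = brain$gene, probe_id = brain$probe_id,
             p = brain$brain_p, p_adj = brain$p_adj),
  data.frame(table = "candidates", gene = cand$gene, probe_id = cand$probe_id,
             p = cand$p, p_adj = cand$p_adj))
utils::write.csv(out, file.path(results_dir(), "published_arithmetic.csv"),
                 row.names = FALSE)
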