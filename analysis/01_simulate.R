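#!/usr/bin/env Rscript
# Stage 1: generate the desk-scale synthetic cohort that stands in for a
# ~100-landrace clonal panel: structured genotypes on a transcriptome
# reference (VCF), transcript abundances (TSV), three correlated bulb-yield
# style traits (TSV), module labels and GO annotation, plus the planted
# truth table used later for recovery scoring.

library(tras)

cfg <- sim_config(seed = 1)
dir <- "results/cohort"
coh <- simulate_cohort(cfg, dir = dir)

cat("cohort written to", dir, "\n")
print(coh$G)
print(coh$E)
print(coh$P)
print(summarize_phenotypes(coh$P))
cat(sprintf("planted: %d causal SNPs (CN), %d (BW/BD), %d cascade edges, %d null pairs\n",
            length(coh$truth$causal_snps$CN),
            length(coh$truth$causal_snps$BW),
            nrow(coh$truth$cascade_edges), nrow(coh$truth$null_pairs)))
cat(sprintf("lncRNA-tagged transcripts: %d; modules: %d\n",
            length(coh$truth$lncrna_ids),
            length(unique(na.omit(coh$truth$modules)))))
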