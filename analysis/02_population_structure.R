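#!/usr/bin/env Rscript
# Stage 2: genotype QC, kinship, principal components and significance
# thresholds. The kinship matrix and the first three PCs are the structure
# corrections every downstream mixed-model scan uses; the thresholds come
# from the (effective) marker count.

library(tras)

dir <- "results/cohort"
out <- "results/structure"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

G <- read_genotypes(file.path(dir, "genotypes.vcf"),
                    maf_floor = 0.05, missing_ceiling = 0.2)
print(G)
G <- impute_genotypes(G)

K <- compute_kinship(G, estimator = "centered")
W <- compute_pcs(G, n_pcs = 3)
cat(sprintf("kinship: mean diagonal %.3f, min eigenvalue %.2e%s\n",
            mean(diag(K$K)), K$min_eigenvalue,
            if (K$ridged) " (ridged)" else ""))
cat(sprintf("PC variance explained: %s\n",
            paste(sprintf("%.1f%%", 100 * W$var_explained), collapse = ", ")))

m <- nrow(G$snps)
m_eff <- effective_marker_count(G)
cat(sprintf("markers: %d total, %.1f effective (Li-Ji)\n", m, m_eff))
th_total <- significance_thresholds(m, m, alpha = 0.05)
th_lj <- significance_thresholds(m, m_eff, alpha = 0.05)
print(th_total)
print(th_lj)

write_matrix_tsv(K$K, file.path(out, "kinship.tsv"))
write_matrix_tsv(W$W, file.path(out, "pcs.tsv"))
write_tsv_commented(
  data.frame(mode = c("total", "li_ji"), m_total = m,
             m_eff = c(m, m_eff),
             bonferroni_p = c(th_total$bonferroni_p, th_lj$bonferroni_p),
             suggestive_p = th_total$suggestive_p),
  file.path(out, "thresholds.tsv"))
cat("structure tables written to", out, "\n")
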