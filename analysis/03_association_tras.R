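#!/usr/bin/env Rscript
# Stage 3: the transcriptome-referenced association study proper. For each
# trait: mixed-model scan over all SNPs, anchoring of significant SNPs to
# the transcripts they lie in, expression-trait Pearson validation, and
# the trait-related transcript calls with regulation direction.

library(tras)

dir <- "results/cohort"
out <- "results/tras"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

G <- impute_genotypes(read_genotypes(file.path(dir, "genotypes.vcf")))
E <- read_expression(file.path(dir, "expression.tsv"), log_transform = TRUE)
P <- read_phenotypes(file.path(dir, "phenotypes.tsv"),
                     units = c(BW = "g", BD = "mm", CN = "count"))
al <- align_samples(G, E, P)
G <- al$G; E <- al$E; P <- al$P

K <- compute_kinship(G)
W <- compute_pcs(G, 3)
th <- significance_thresholds(nrow(G$snps))
print(th)

all_trt <- list()
for (tr in colnames(P$traits)) {
  res <- tras_trait(tr, P, E, W, K, G, th)
  cat(sprintf("%s: %d associated SNPs on %d transcripts -> %d trait-related\n",
              tr, res$counts$n_snps, res$counts$n_transcripts,
              res$counts$n_trait_related))
  write_scan_tsv(res$scan, file.path(out, sprintf("scan_%s.tsv", tr)),
                 list(trait = tr, bonferroni_p = th$bonferroni_p))
  all_trt[[tr]] <- res$trait_related
}
trt <- do.call(rbind, all_trt)
rownames(trt) <- NULL
print(trt)
pleio <- names(which(table(trt$transcript_id) >= 2))
if (length(pleio))
  cat("pleiotropic (multi-trait) transcripts:",
      paste(pleio, collapse = ", "), "\n")
write_tsv_commented(trt, file.path(out, "trait_related.tsv"),
                    list(bonferroni_p = th$bonferroni_p, expr_alpha = 0.05))
cat("TRAS tables written to", out, "\n")
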