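#!/usr/bin/env Rscript
# Stage 4: eQTL scans over the trait-related transcripts (every SNP against
# each transcript's expression as the phenotype) and the three-criterion
# directed interrelation network, with G (eQTL p) and E (expression
# correlation p) annotations on each edge.

library(tras)

dir <- "results/cohort"
out <- "results/eqtl"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

G <- impute_genotypes(read_genotypes(file.path(dir, "genotypes.vcf")))
E <- read_expression(file.path(dir, "expression.tsv"), log_transform = TRUE)
P <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
al <- align_samples(G, E, P)
G <- al$G; E <- al$E
K <- compute_kinship(G)
W <- compute_pcs(G, 3)
th <- significance_thresholds(nrow(G$snps))

trt <- read.delim("results/tras/trait_related.tsv", comment.char = "#")
targets <- unique(trt$transcript_id)
cat(sprintf("eQTL scan: %d SNPs x %d target transcripts at p <= %.3g\n",
            nrow(G$snps), length(targets), th$bonferroni_p))

eq <- eqtl_scan(E, targets, W, K, G, threshold_p = th$bonferroni_p)
eq$target_counts <- classify_regulatory_position(eq$target_counts)
cat(sprintf("%d expression-associated SNPs on %d eQTL-located transcripts\n",
            nrow(eq$records), length(unique(eq$records$located_transcript_id))))
print(eq$target_counts)

net <- build_interrelation_network(trt, eq, E)
cat(sprintf("interrelation network: %d directed edges (%d cis records set aside)\n",
            nrow(net$edges), nrow(net$cis_records)))
print(net$edges)

write_tsv_commented(eq$records, file.path(out, "eqtl.tsv"),
                    list(threshold_p = th$bonferroni_p))
write_tsv_commented(eq$target_counts, file.path(out, "eqtl_target_counts.tsv"))
edges <- net$edges
colnames(edges) <- c("trait", "source", "target", "G", "E", "r")
write_tsv_commented(edges, file.path(out, "network.tsv"))
write_network_dot(net$edges, file.path(out, "network.dot"))
cat("eQTL and network tables written to", out, "\n")
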