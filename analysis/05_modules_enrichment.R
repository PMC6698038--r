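#!/usr/bin/env Rscript
# Stage 5: co-expression module eigengenes correlated with the traits, and
# GO over-representation of the co-expression partners of lncRNA-tagged
# trait-related transcripts (hypergeometric p, BH q).

library(tras)
suppressMessages(library(jsonlite))

dir <- "results/cohort"
out <- "results/modules"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

E <- read_expression(file.path(dir, "expression.tsv"), log_transform = TRUE)
P <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
modules <- read_modules(file.path(dir, "modules.tsv"))
go <- read_go_annotation(file.path(dir, "go_annotation.tsv"))
truth <- fromJSON(file.path(dir, "truth.json"))

eig <- lapply(sort(unique(modules)), function(m)
  module_eigengene(E, modules, m))
names(eig) <- sort(unique(modules))
mt <- module_trait_correlation(eig, P)
sig <- mt[mt$significant, ]
cat(sprintf("%d of %d module-trait pairs significant at p < 0.05\n",
            nrow(sig), nrow(mt)))
best <- sig[order(sig$p), ][1, ]
cat(sprintf("strongest coupling: module %s x %s, r = %.3f (p = %.2g)\n",
            best$module, best$trait, best$r, best$p))
write_tsv_commented(mt, file.path(out, "module_trait.tsv"))

trt <- read.delim("results/tras/trait_related.tsv", comment.char = "#")
lnc <- intersect(unlist(truth$lncrna_ids), trt$transcript_id)
cat(sprintf("lncRNA candidates among trait-related transcripts: %s\n",
            paste(lnc, collapse = ", ")))
for (id in lnc) {
  partners <- lncrna_partners(id, modules)
  enr <- go_enrichment(partners, E$transcripts, go)
  cat(sprintf("%s: %d co-expression partners, %d enriched terms (q <= 0.05)\n",
              id, length(partners), nrow(enr)))
  if (nrow(enr))
    write_tsv_commented(enr, file.path(out, sprintf("enrichment_%s.tsv", id)))
}
cat("module and enrichment tables written to", out, "\n")
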