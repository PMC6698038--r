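Package: tras
Title: Transcriptome-Referenced Association Study and eQTL Interrelation
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Association mapping of quantitative traits against SNPs anchored
    to a de novo transcriptome reference, for clonal crop panels without a
    genome assembly. Implements an exact single-variance-component linear
    mixed model (kinship eigendecomposition, REML profile likelihood,
    EMMAX-style marker scoring), principal-component and kinship structure
    correction, Bonferroni thresholds from the effective number of
    independent markers, expression-trait validation of candidate
    transcripts, eQTL scans with a three-criterion directed interrelation
    network, module eigengene-trait correlation, hypergeometric GO
    enrichment for lncRNA function prediction, and a synthetic cohort
    generator with planted regulatory cascades for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
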