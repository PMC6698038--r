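## eQTL scan over trait-related transcripts and the three-criterion
## directed interrelation network:
##   an edge B -> A exists when (1) a SNP located in transcript B is
##   significantly associated with A's expression (B is an
##   eQTL-located-transcript of A), (2) A and B are trait-related for the
##   same trait, and (3) the expression of A and B is correlated (p < 0.05).

#' eQTL scan: every SNP against each target transcript's expression
#'
#' One full mixed-model marker scan per target, with the null variance
#' ratio re-fitted per expression phenotype (expression phenotypes differ
#' in heritability). Records are kept at p <= `threshold_p`; per-target
#' counts of associated SNPs and distinct eQTL-located-transcripts are
#' reported. A target whose scan fails is skipped with a warning.
#'
#' @param E an `expression_matrix` (transformed scale).
#' @param targets transcript ids whose expression is the phenotype.
#' @param W,K,G structure covariates, kinship, imputed genotypes.
#' @param threshold_p eQTL significance threshold (applied per target).
#' @return list: `records` (data.frame snp_id, located_transcript_id,
#'   target_transcript_id, p_value), `target_counts` (data.frame
#'   target_transcript_id, n_snps, n_located_transcripts).
#' @export
eqtl_scan <- function(E, targets, W, K, G, threshold_p) {
  miss <- setdiff(targets, E$transcripts)
  if (length(miss)) stop_tras("target not in expression matrix: %s", miss[1])
  recs <- list()
  counts <- list()
  for (tid in targets) {
    scan <- tryCatch(
      association_scan(E$values[, tid], W, K, G, threshold_p = threshold_p),
      error = function(e) {
        warning(sprintf("eQTL scan skipped for %s: %s", tid,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(scan)) next
    sig <- scan$significant
    counts[[tid]] <- data.frame(
      target_transcript_id = tid, n_snps = nrow(sig),
      n_located_transcripts = length(unique(sig$transcript_id)),
      stringsAsFactors = FALSE)
    if (nrow(sig))
      recs[[tid]] <- data.frame(snp_id = sig$snp_id,
                                located_transcript_id = sig$transcript_id,
                                target_transcript_id = tid,
                                p_value = sig$p, stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(snp_id = character(), located_transcript_id = character(),
               target_transcript_id = character(), p_value = numeric(),
               stringsAsFactors = FALSE)
  rownames(records) <- NULL
  tc <- if (length(counts)) do.call(rbind, counts) else
    data.frame(target_transcript_id = character(), n_snps = integer(),
               n_located_transcripts = integer(), stringsAsFactors = FALSE)
  rownames(tc) <- NULL
  list(records = records, target_counts = tc)
}

#' Classify targets by their regulatory position from eQTL counts
#'
#' A transcript whose expression is associated with no SNP anywhere is an
#' upstream candidate (its expression is rarely regulated by other loci);
#' one associated with many SNPs is a downstream candidate (modulated by
#' many loci); the rest are intermediate.
#'
#' @param target_counts from [eqtl_scan()].
#' @param upstream_max max eQTL count for an upstream candidate (default 0).
#' @param downstream_min min count for a downstream candidate (default 50).
#' @return `target_counts` with an added `position` column.
#' @export
classify_regulatory_position <- function(target_counts, upstream_max = 0,
                                         downstream_min = 50) {
  if (is.null(target_counts) || nrow(target_counts) == 0) return(target_counts)
  n <- target_counts$n_snps
  target_counts$position <- ifelse(
    n <= upstream_max, "upstream-candidate",
    ifelse(n >= downstream_min, "downstream-candidate", "intermediate"))
  target_counts
}

#' Build the directed interrelation network (three-criterion rule)
#'
#' For every eQTL record whose located transcript B and target A are both
#' trait-related for the same trait and B != A, the edge B -> A is kept
#' when the expression of A and B is correlated at p < `corr_alpha`
#' (either sign by default; `require_positive_corr` restricts to r > 0).
#' The edge's G annotation is the best qualifying eQTL p of B's SNPs on A,
#' the E annotation the correlation p. Self (cis) records are excluded
#' from the network and returned separately. Output is sorted by trait
#' then G p-value.
#'
#' @param trait_related data.frame from the TRAS stage (columns trait,
#'   transcript_id), possibly several traits stacked.
#' @param eqtl records from [eqtl_scan()].
#' @param E an `expression_matrix`.
#' @param corr_alpha expression-correlation criterion level (default 0.05).
#' @param require_positive_corr restrict criterion 3 to r > 0
#'   (default FALSE: the operative rule is two-sided).
#' @return list: `edges` (data.frame trait, source_id, target_id, g_pvalue,
#'   e_pvalue, e_r), `cis_records` (self-target eQTL records).
#' @export
build_interrelation_network <- function(trait_related, eqtl, E,
                                        corr_alpha = 0.05,
                                        require_positive_corr = FALSE) {
  empty <- data.frame(trait = character(), source_id = character(),
                      target_id = character(), g_pvalue = numeric(),
                      e_pvalue = numeric(), e_r = numeric(),
                      stringsAsFactors = FALSE)
  rec <- eqtl$records
  cis <- rec[rec$located_transcript_id == rec$target_transcript_id, ,
             drop = FALSE]
  rec <- rec[rec$located_transcript_id != rec$target_transcript_id, ,
             drop = FALSE]
  if (nrow(rec) == 0 || nrow(trait_related) == 0)
    return(list(edges = empty, cis_records = cis))
  edges <- list()
  for (tr in unique(trait_related$trait)) {
    set <- trait_related$transcript_id[trait_related$trait == tr]
    sub <- rec[rec$located_transcript_id %in% set &
                 rec$target_transcript_id %in% set, , drop = FALSE]
    if (nrow(sub) == 0) next
    key <- paste(sub$located_transcript_id, sub$target_transcript_id)
    gp <- tapply(sub$p_value, key, min)
    pairs <- do.call(rbind, strsplit(names(gp), " "))
    for (i in seq_along(gp)) {
      b <- pairs[i, 1]; a <- pairs[i, 2]
      ct <- pearson_test(E$values[, a], E$values[, b])
      if (ct$degenerate || ct$p >= corr_alpha) next
      if (require_positive_corr && ct$r <= 0) next
      edges[[length(edges) + 1]] <- data.frame(
        trait = tr, source_id = b, target_id = a,
        g_pvalue = unname(gp[i]), e_pvalue = ct$p, e_r = ct$r,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else empty
  edges <- edges[order(edges$trait, edges$g_pvalue), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, cis_records = cis)
}

#' Export an interrelation network as GraphViz DOT
#'
#' Edges are annotated in the G/E style (G = eQTL p, E = expression
#' correlation p).
#'
#' @param edges edge table from [build_interrelation_network()].
#' @param path output `.dot` file.
#' @export
write_network_dot <- function(edges, path) {
  lines <- c("digraph interrelation {", "  rankdir=LR;")
  for (i in seq_len(nrow(edges))) {
    lines <- c(lines, sprintf(
      '  "%s" -> "%s" [label="G=%.2g\\nE=%.2g"];',
      edges$source_id[i], edges$target_id[i],
      edges$g_pvalue[i], edges$e_pvalue[i]))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
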