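## Trait-related transcript calling: anchor significant SNPs to the
## transcripts they lie in, validate candidates by expression-trait
## correlation, assign a regulation direction, and summarize the
## population phenotypes.

#' Population phenotype summary
#'
#' Per trait: min, max, mean, sd and the fold-range max/min (display-rounded
#' to one decimal only when printed); plus all pairwise trait Pearson
#' correlations with two-sided p from the t transform on n - 2 df.
#' A trait with min <= 0 gets an undefined (NA) fold-range, not an error;
#' a constant trait flags its correlations undefined.
#'
#' @param P a `phenotype_table`.
#' @return a `phenotype_summary` (list: per_trait data.frame, correlations
#'   data.frame).
#' @export
summarize_phenotypes <- function(P) {
  tr <- P$traits
  per <- do.call(rbind, lapply(colnames(tr), function(k) {
    x <- tr[[k]][!is.na(tr[[k]])]
    fr <- if (min(x) > 0) max(x) / min(x) else NA_real_
    data.frame(trait = k, n = length(x), min = min(x), max = max(x),
               mean = mean(x), sd = stats::sd(x), fold_range = fr,
               stringsAsFactors = FALSE)
  }))
  if (ncol(tr) < 2)
    return(structure(list(per_trait = per,
                          correlations = data.frame(
                            trait_a = character(), trait_b = character(),
                            r = numeric(), p = numeric(),
                            degenerate = logical())),
                     class = "phenotype_summary"))
  cmb <- utils::combn(colnames(tr), 2)
  cors <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    ct <- pearson_test(tr[[a]], tr[[b]])
    data.frame(trait_a = a, trait_b = b, r = ct$r, p = ct$p,
               degenerate = ct$degenerate, stringsAsFactors = FALSE)
  }))
  structure(list(per_trait = per, correlations = cors),
            class = "phenotype_summary")
}

#' @export
print.phenotype_summary <- function(x, ...) {
  pt <- x$per_trait
  for (i in seq_len(nrow(pt)))
    cat(sprintf("%s: range %.1f-%.1f, mean %.1f +/- %.1f, fold-range %s\n",
                pt$trait[i], pt$min[i], pt$max[i], pt$mean[i], pt$sd[i],
                ifelse(is.na(pt$fold_range[i]), "undefined",
                       sprintf("%.1f", pt$fold_range[i]))))
  for (i in seq_len(nrow(x$correlations)))
    cat(sprintf("r(%s, %s) = %.2f (p = %.2g)\n",
                x$correlations$trait_a[i], x$correlations$trait_b[i],
                x$correlations$r[i], x$correlations$p[i]))
  invisible(x)
}

#' Group significant SNPs by the transcript they lie in
#'
#' @param hits data.frame of significant scan results (needs snp_id).
#' @param snps SNP table of the genotype matrix (snp_id, transcript_id).
#' @return list: `mapping` (named list transcript_id -> snp_id vector),
#'   `n_snps`, `n_transcripts`.
#' @export
map_snps_to_transcripts <- function(hits, snps) {
  if (nrow(hits) == 0)
    return(list(mapping = list(), n_snps = 0L, n_transcripts = 0L))
  i <- match(hits$snp_id, snps$snp_id)
  if (anyNA(i))
    stop_tras("unknown snp_id: %s", hits$snp_id[which(is.na(i))[1]])
  mapping <- split(hits$snp_id, snps$transcript_id[i])
  list(mapping = mapping, n_snps = nrow(hits),
       n_transcripts = length(mapping))
}

#' Expression-trait Pearson correlation for candidate transcripts
#'
#' Run on the expression matrix's current scale (log2(x+1) in the default
#' pipeline, so this filter and the eQTL scan see identical data). Raw
#' two-sided p-values are compared to 0.05 downstream with no multiplicity
#' adjustment, matching the published validation rule.
#'
#' @param E an `expression_matrix`.
#' @param y trait vector aligned to `E$samples`.
#' @param candidates transcript ids (must be in `E$transcripts`).
#' @return data.frame: transcript_id, r, p, n, degenerate.
#' @export
expression_trait_correlation <- function(E, y, candidates) {
  miss <- setdiff(candidates, E$transcripts)
  if (length(miss))
    stop_tras("candidate transcript(s) not in expression matrix: %s",
              miss[1])
  do.call(rbind, lapply(candidates, function(tid) {
    ct <- pearson_test(E$values[, tid], y)
    data.frame(transcript_id = tid, r = ct$r, p = ct$p, n = ct$n,
               degenerate = ct$degenerate, stringsAsFactors = FALSE)
  }))
}

#' Call trait-related transcripts
#'
#' The intersection of the genotype filter (some SNP in the transcript
#' passes the Bonferroni threshold) and the expression filter (Pearson
#' p < `expr_alpha`); the regulation direction is the sign of the
#' expression-trait correlation ("+" = expression positively tracks the
#' trait). Ordered by (trait, transcript_id). `bh_adjust` optionally
#' replaces the raw expression p filter by a Benjamini-Hochberg one.
#'
#' @param mapping output of [map_snps_to_transcripts()].
#' @param correlations output of [expression_trait_correlation()].
#' @param hits the significant scan rows used for `mapping` (for best p).
#' @param trait trait name stamped on the output.
#' @param expr_alpha expression filter level (default 0.05, raw).
#' @param bh_adjust use BH-adjusted p in the filter (default FALSE).
#' @return data.frame: trait, transcript_id, n_snps, best_genotype_p,
#'   expression_r, expression_p, direction.
#' @export
call_trait_related <- function(mapping, correlations, hits, trait,
                               expr_alpha = 0.05, bh_adjust = FALSE) {
  empty <- data.frame(trait = character(), transcript_id = character(),
                      n_snps = integer(), best_genotype_p = numeric(),
                      expression_r = numeric(), expression_p = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  if (length(mapping$mapping) == 0 || nrow(correlations) == 0) return(empty)
  pfilt <- if (bh_adjust)
    stats::p.adjust(correlations$p, "BH") else correlations$p
  pass_expr <- correlations$transcript_id[pfilt < expr_alpha &
                                            !correlations$degenerate]
  keep <- intersect(names(mapping$mapping), pass_expr)
  if (length(keep) == 0) return(empty)
  out <- do.call(rbind, lapply(sort(keep), function(tid) {
    sid <- mapping$mapping[[tid]]
    gp <- min(hits$p[hits$snp_id %in% sid])
    ci <- correlations[correlations$transcript_id == tid, ]
    data.frame(trait = trait, transcript_id = tid, n_snps = length(sid),
               best_genotype_p = gp, expression_r = ci$r,
               expression_p = ci$p,
               direction = ifelse(ci$r > 0, "+", "-"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full TRAS stage for one trait
#'
#' Scan, SNP-to-transcript anchoring, expression validation and
#' trait-related calling in one call.
#'
#' @param trait trait name (column of `P$traits`).
#' @param P a `phenotype_table` (aligned).
#' @param E an `expression_matrix` (aligned, transformed scale).
#' @param W,K,G structure covariates, kinship, imputed genotypes.
#' @param thresholds a `threshold_set`.
#' @param expr_alpha expression filter level (default 0.05).
#' @return list: scan, mapping, correlations, trait_related, counts.
#' @export
tras_trait <- function(trait, P, E, W, K, G, thresholds, expr_alpha = 0.05) {
  y <- P$traits[[trait]]
  scan <- association_scan(y, W, K, G, threshold_p = thresholds$bonferroni_p)
  mapping <- map_snps_to_transcripts(scan$significant, G$snps)
  cand <- names(mapping$mapping)
  correlations <- if (length(cand))
    expression_trait_correlation(E, y, cand)
  else data.frame(transcript_id = character(), r = numeric(), p = numeric(),
                  n = integer(), degenerate = logical())
  trt <- call_trait_related(mapping, correlations, scan$significant, trait,
                            expr_alpha = expr_alpha)
  # pleiotropy across traits is reported by the pipeline, which sees all
  # traits; here we report the per-trait Table-1-style counts
  counts <- data.frame(trait = trait,
                       n_snps = mapping$n_snps,
                       n_transcripts = mapping$n_transcripts,
                       n_trait_related = nrow(trt),
                       stringsAsFactors = FALSE)
  list(trait = trait, scan = scan, mapping = mapping,
       correlations = correlations, trait_related = trt, counts = counts)
}
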