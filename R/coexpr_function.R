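## Co-expression module summaries and GO-based function prediction.
## Module detection itself is upstream (labels arrive as input); here we
## compute module eigengenes, correlate them with traits, identify
## co-expression partners of lncRNA candidates, and test GO
## over-representation with hypergeometric p and BH q values.

#' Module eigengene (first principal component of a module's expression)
#'
#' The per-transcript standardized expression submatrix's first left
#' singular vector (unit norm), with the sign fixed so the eigengene
#' correlates positively with the module's mean standardized profile.
#' A singleton module returns its standardized expression vector
#' (normalized), flagged.
#'
#' @param E an `expression_matrix`.
#' @param modules named character vector transcript_id -> module label.
#' @param module_label which module.
#' @return numeric vector of length n with attributes `module`, `n_transcripts`,
#'   `singleton`.
#' @export
module_eigengene <- function(E, modules, module_label) {
  tids <- names(modules)[modules == module_label]
  tids <- intersect(tids, E$transcripts)
  if (length(tids) == 0) stop_tras("module '%s' has no transcripts in E",
                                   module_label)
  X <- E$values[, tids, drop = FALSE]
  Xs <- apply(X, 2, std_vec)
  if (length(tids) == 1) {
    v <- Xs[, 1]
    v <- v / sqrt(sum(v^2))
    return(structure(v, module = module_label, n_transcripts = 1L,
                     singleton = TRUE))
  }
  sv <- svd(Xs, nu = 1, nv = 0)
  eg <- sv$u[, 1]
  if (stats::cor(eg, rowMeans(Xs)) < 0) eg <- -eg
  structure(eg, module = module_label, n_transcripts = length(tids),
            singleton = FALSE)
}

#' Correlate module eigengenes with traits
#'
#' Pearson r with two-sided p per (module, trait) pair; significance at
#' raw p < `alpha`.
#'
#' @param eigengenes named list of eigengene vectors (one per module).
#' @param P a `phenotype_table` aligned to the eigengenes.
#' @param alpha significance level (default 0.05).
#' @return data.frame: module, trait, r, p, significant.
#' @export
module_trait_correlation <- function(eigengenes, P, alpha = 0.05) {
  out <- list()
  for (m in names(eigengenes)) {
    for (tr in colnames(P$traits)) {
      ct <- pearson_test(eigengenes[[m]], P$traits[[tr]])
      out[[length(out) + 1]] <- data.frame(
        module = m, trait = tr, r = ct$r, p = ct$p,
        significant = !ct$degenerate && ct$p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Co-expression partners of a lncRNA candidate
#'
#' Partnership is shared module membership: all other transcripts carrying
#' the lncRNA's module label. An unassigned lncRNA yields an empty set with
#' a warning. `min_abs_r` switches to a module-free correlation
#' neighborhood (|r| >= cutoff against the lncRNA's expression) instead.
#'
#' @param lncrna_id transcript id of the lncRNA.
#' @param modules named character vector transcript_id -> module label.
#' @param E expression matrix, required only for `min_abs_r`.
#' @param min_abs_r optional |r| cutoff for correlation-based partnership.
#' @return character vector of partner transcript ids.
#' @export
lncrna_partners <- function(lncrna_id, modules, E = NULL, min_abs_r = NULL) {
  if (!is.null(min_abs_r)) {
    stopifnot(!is.null(E), lncrna_id %in% E$transcripts)
    r <- drop(stats::cor(E$values[, lncrna_id], E$values))
    return(setdiff(E$transcripts[!is.na(r) & abs(r) >= min_abs_r], lncrna_id))
  }
  if (!lncrna_id %in% names(modules)) {
    warning(sprintf("lncRNA '%s' has no module assignment", lncrna_id))
    return(character())
  }
  lab <- modules[[lncrna_id]]
  setdiff(names(modules)[modules == lab], lncrna_id)
}

#' GO over-representation test (hypergeometric with BH correction)
#'
#' Per term: upper-tail hypergeometric p for observing k annotated
#' transcripts in the target set of size n, given K annotated among the N
#' background transcripts; Benjamini-Hochberg q across all tested terms.
#' Terms absent from the background (K = 0) are skipped. Results are
#' filtered at q <= `q_cutoff` unless `keep_all`.
#'
#' @param target transcript set of interest (subset of `background`).
#' @param background universe of transcripts.
#' @param annotation data.frame transcript_id, term_id, term_name (terms
#'   are flat sets; no ontology-graph propagation).
#' @param q_cutoff FDR cutoff (default 0.05).
#' @param keep_all return all tested terms regardless of q (default FALSE).
#' @return data.frame: term_id, term_name, k_in_set, K_in_background,
#'   n_set, N_background, p_value, q_value; sorted by q then p.
#' @export
go_enrichment <- function(target, background, annotation, q_cutoff = 0.05,
                          keep_all = FALSE) {
  if (!all(target %in% background))
    stop_tras("target set must be a subset of the background")
  ann <- annotation[annotation$transcript_id %in% background, , drop = FALSE]
  N <- length(unique(background))
  n <- length(unique(target))
  terms <- sort(unique(ann$term_id))
  rows <- lapply(terms, function(tm) {
    tset <- unique(ann$transcript_id[ann$term_id == tm])
    K <- length(tset)
    if (K == 0) return(NULL)
    k <- length(intersect(tset, target))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm,
               term_name = ann$term_name[match(tm, ann$term_id)],
               k_in_set = k, K_in_background = K, n_set = n,
               N_background = N, p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(term_id = character(), term_name = character(),
                      k_in_set = integer(), K_in_background = integer(),
                      n_set = integer(), N_background = integer(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$q_value, res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  if (keep_all) res else res[res$q_value <= q_cutoff, , drop = FALSE]
}
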