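## End-to-end orchestration: QC -> structure -> per-trait association ->
## trait-related calling -> eQTL -> interrelation network -> module/trait
## correlation -> lncRNA GO enrichment, with a manifest of parameters and
## per-stage counts. Deterministic given (inputs, config).

#' Pipeline configuration
#'
#' @param maf_floor,missing_ceiling genotype QC parameters.
#' @param n_pcs number of PC covariates (default 3).
#' @param m_eff_mode `"total"` treats all markers as independent when
#'   setting the Bonferroni threshold (the replication default);
#'   `"li_ji"` uses the eigenvalue-based effective marker count.
#' @param alpha study-wide significance level (default 0.05).
#' @param expr_alpha expression-trait validation level (default 0.05, raw).
#' @param corr_alpha network criterion-3 level (default 0.05).
#' @param eqtl_threshold `NULL` to reuse the trait Bonferroni threshold for
#'   the eQTL scans (per target), or a number.
#' @param assoc_threshold `NULL` to use the Bonferroni threshold for trait
#'   scans (default), or an explicit per-test p threshold (1 marks every
#'   scanned SNP significant).
#' @param kinship_estimator `"centered"` or `"standardized"`.
#' @param log_transform apply log2(x+1) to expression (default TRUE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(maf_floor = 0.05, missing_ceiling = 0.2,
                            n_pcs = 3, m_eff_mode = c("total", "li_ji"),
                            alpha = 0.05, expr_alpha = 0.05,
                            corr_alpha = 0.05, eqtl_threshold = NULL,
                            assoc_threshold = NULL,
                            kinship_estimator = "centered",
                            log_transform = TRUE) {
  m_eff_mode <- match.arg(m_eff_mode)
  stopifnot(alpha > 0, alpha < 1, maf_floor >= 0, maf_floor <= 0.5)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline on a cohort
#'
#' `cohort` is either the in-memory result of [simulate_cohort()] or a list
#' of paths (`vcf`, `expression`, `phenotypes`, and optionally `modules`,
#' `go`). Stages run in dependency order; when `out_dir` is given every
#' stage's table is written as TSV plus a `manifest` of parameters and
#' counts. Rerunning on identical inputs reproduces identical outputs.
#'
#' @param cohort input data (see above).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list: aligned data, structure objects, thresholds, per-trait
#'   TRAS results, eQTL records, network, module/trait correlations,
#'   lncRNA enrichment, and `manifest`.
#' @export
run_full_pipeline <- function(cohort, config = pipeline_config(),
                              out_dir = NULL) {
  if (!is.null(cohort$vcf)) {
    G <- read_genotypes(cohort$vcf, maf_floor = config$maf_floor,
                        missing_ceiling = config$missing_ceiling)
    E <- read_expression(cohort$expression,
                         log_transform = config$log_transform)
    P <- read_phenotypes(cohort$phenotypes)
    modules <- if (!is.null(cohort$modules)) read_modules(cohort$modules)
    go <- if (!is.null(cohort$go)) read_go_annotation(cohort$go)
    lnc <- cohort$lncrna_ids
  } else {
    G <- qc_genotypes(cohort$G, config$maf_floor, config$missing_ceiling)
    E <- cohort$E
    if (config$log_transform && !E$transformed)
      E <- new_expression_matrix(E$samples, log2(E$values + 1),
                                 transformed = TRUE)
    P <- cohort$P
    modules <- cohort$modules
    go <- cohort$go
    lnc <- cohort$truth$lncrna_ids
  }
  al <- align_samples(G, E, P)
  G <- impute_genotypes(al$G); E <- al$E; P <- al$P

  K <- compute_kinship(G, estimator = config$kinship_estimator)
  W <- compute_pcs(G, n_pcs = config$n_pcs)
  m_eff <- if (config$m_eff_mode == "total") nrow(G$snps) else
    effective_marker_count(G)
  thresholds <- significance_thresholds(nrow(G$snps), m_eff,
                                        alpha = config$alpha)

  summary_pheno <- summarize_phenotypes(P)
  scan_thresholds <- thresholds
  if (!is.null(config$assoc_threshold))
    scan_thresholds$bonferroni_p <- config$assoc_threshold
  tras <- lapply(colnames(P$traits), function(tr)
    tras_trait(tr, P, E, W, K, G, scan_thresholds,
               expr_alpha = config$expr_alpha))
  names(tras) <- colnames(P$traits)
  trait_related <- do.call(rbind, lapply(tras, `[[`, "trait_related"))
  rownames(trait_related) <- NULL

  eqtl_p <- config$eqtl_threshold %||% thresholds$bonferroni_p
  targets <- unique(trait_related$transcript_id)
  eqtl <- eqtl_scan(E, targets, W, K, G, threshold_p = eqtl_p)
  eqtl$target_counts <- classify_regulatory_position(eqtl$target_counts)
  network <- build_interrelation_network(trait_related, eqtl, E,
                                         corr_alpha = config$corr_alpha)

  module_cor <- NULL
  enrichment <- NULL
  if (!is.null(modules)) {
    modules <- modules[!is.na(modules)]
    modules <- modules[names(modules) %in% E$transcripts]
    eigengenes <- lapply(sort(unique(modules)), function(m)
      module_eigengene(E, modules, m))
    names(eigengenes) <- sort(unique(modules))
    module_cor <- module_trait_correlation(eigengenes, P,
                                           alpha = config$expr_alpha)
    if (!is.null(go) && length(lnc)) {
      lnc_called <- intersect(lnc, trait_related$transcript_id)
      enrichment <- lapply(lnc_called, function(id) {
        partners <- lncrna_partners(id, modules)
        if (!length(partners)) return(NULL)
        go_enrichment(partners, E$transcripts, go)
      })
      names(enrichment) <- lnc_called
    }
  }

  pleio <- table(trait_related$transcript_id)
  manifest <- list(
    version = as.character(utils::packageVersion("tras")),
    config = unclass(config),
    n_samples = length(al$samples),
    qc = G$qc,
    thresholds = unclass(thresholds),
    counts = do.call(rbind, lapply(tras, `[[`, "counts")),
    n_eqtl_records = nrow(eqtl$records),
    n_eqtl_located_transcripts =
      length(unique(eqtl$records$located_transcript_id)),
    n_network_edges = nrow(network$edges),
    pleiotropic_transcripts = names(pleio)[pleio >= 2])

  out <- list(G = G, E = E, P = P, K = K, W = W, thresholds = thresholds,
              phenotype_summary = summary_pheno, tras = tras,
              trait_related = trait_related, eqtl = eqtl,
              network = network, module_trait = module_cor,
              enrichment = enrichment, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# QC an in-memory genotype matrix the same way read_genotypes does.
qc_genotypes <- function(G, maf_floor = 0.05, missing_ceiling = 0.2) {
  d <- G$dosages
  miss <- colMeans(is.na(d))
  keep_miss <- miss <= missing_ceiling
  nd <- apply(d, 2, function(x) length(unique(x[!is.na(x)])))
  keep_poly <- nd >= 2
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep_maf <- maf >= maf_floor
  keep <- keep_miss & keep_poly & keep_maf
  if (!any(keep)) stop_tras("no SNPs survive QC")
  qc <- list(n_input = ncol(d), n_high_missing = sum(!keep_miss),
             n_monomorphic = sum(keep_miss & !keep_poly),
             n_low_maf = sum(keep_miss & keep_poly & !keep_maf),
             n_kept = sum(keep))
  new_genotype_matrix(G$samples, G$snps[keep, , drop = FALSE],
                      d[, keep, drop = FALSE], qc = qc)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prm <- list(bonferroni_p = out$thresholds$bonferroni_p,
              suggestive_p = out$thresholds$suggestive_p,
              m_eff = out$thresholds$m_eff)
  for (tr in names(out$tras))
    write_scan_tsv(out$tras[[tr]]$scan,
                   file.path(dir, sprintf("scan_%s.tsv", tr)), prm)
  write_tsv_commented(out$trait_related,
                      file.path(dir, "trait_related.tsv"), prm)
  write_tsv_commented(out$eqtl$records, file.path(dir, "eqtl.tsv"), prm)
  if (nrow(out$eqtl$target_counts))
    write_tsv_commented(out$eqtl$target_counts,
                        file.path(dir, "eqtl_target_counts.tsv"), prm)
  net <- out$network$edges
  colnames(net) <- c("trait", "source", "target", "G", "E", "r")
  write_tsv_commented(net, file.path(dir, "network.tsv"), prm)
  write_network_dot(out$network$edges, file.path(dir, "network.dot"))
  if (!is.null(out$module_trait))
    write_tsv_commented(out$module_trait,
                        file.path(dir, "module_trait.tsv"), prm)
  if (!is.null(out$enrichment)) {
    for (id in names(out$enrichment))
      if (!is.null(out$enrichment[[id]]) && nrow(out$enrichment[[id]]))
        write_tsv_commented(out$enrichment[[id]],
                            file.path(dir, sprintf("enrichment_%s.tsv", id)),
                            prm)
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(dir)
}
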