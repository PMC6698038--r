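## Desk-scale cohort generator. Emulates the statistical shape of a
## ~100-accession clonal landrace panel genotyped against a transcriptome
## reference: Balding-Nichols structured genotypes drawn once per accession
## (no segregation, no HWE enforcement), module-structured expression with
## cis effects and planted regulatory cascades, and three positively
## correlated quantitative traits rescaled to bulb-yield-like units
## (BW in g, BD in mm, CN as a count). A truth table records every planted
## entity so recovery can be scored.

#' Simulation configuration
#'
#' Defaults are the desk-scale study conditions: 102 accessions, 2,000
#' transcript-anchored SNPs on 1,000 transcripts, three subpopulations at
#' Fst 0.15, trait scales 21.0 +/- 7.4 g (BW), 41.2 +/- 6.7 mm (BD),
#' 12.7 +/- 4.9 (CN) with target pairwise correlations 0.92 (BW-BD),
#' 0.36 (BD-CN) and 0.23 (BW-CN).
#'
#' The planted architecture follows two cascade motifs on the CN-analog
#' trait (a single-link regulator -> target pair and a convergent
#' two-regulator -> one-target triple), one direct causal SNP explaining
#' ~30% of BW, and one positively plus one negatively acting
#' expression-mediated transcript on BW/BD. Cascade cis SNPs within a
#' motif are simulated in linkage (`ld_pair`, `ld_triple`) — the
#' transcriptome-reference analogue of a pleiotropic genomic region —
#' because five mutually independent SNPs cannot each explain the large
#' trait fractions the cascade needs.
#'
#' `effect_scale = 0` zeroes every planted genetic effect (null cohort);
#' `h2_bg` sets the shared polygenic background per trait.
#'
#' @param n_samples,n_snps,n_transcripts,n_subpops,fst cohort shape.
#' @param maf_range ancestral allele-frequency range.
#' @param missing_rate genotype missingness rate.
#' @param n_modules number of co-expression modules (module 1 is coupled
#'   to the CN-analog trait at correlation `module_trait_r`).
#' @param module_snr variance ratio of module factor to noise (default 2).
#' @param module_fraction fraction of background transcripts assigned to a
#'   module.
#' @param cis_fraction fraction of background transcripts given a cis
#'   effect of size `cis_r2_bg`.
#' @param cis_r2_bg variance of a background transcript's expression
#'   explained by its cis SNP (default 0.4).
#' @param module_trait_r target correlation of module 1's factor with the
#'   CN-analog trait (default 0.452).
#' @param effect_scale multiplier on all planted genetic effects.
#' @param h2_bg per-trait shared polygenic background fractions (BW, BD, CN).
#' @param fg per-trait planted-genetic variance fractions (BW, BD, CN).
#' @param trait_means,trait_sds,trait_cors trait scale targets.
#' @param ld_pair,ld_triple dosage correlation of linked cascade cis SNPs.
#' @param lnc_fraction fraction of background transcripts tagged lncRNA.
#' @param n_go_terms,go_enriched_frac GO annotation shape: terms overall,
#'   and the fraction of a module's transcripts carrying its planted term.
#' @param n_null_pairs planted unrelated transcript pairs for false-edge
#'   scoring.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 102, n_snps = 2000, n_transcripts = 1000,
                       n_subpops = 3, fst = 0.15,
                       maf_range = c(0.1, 0.9), missing_rate = 0.01,
                       n_modules = 10, module_snr = 2,
                       module_fraction = 0.8,
                       cis_fraction = 0.1, cis_r2_bg = 0.4,
                       module_trait_r = 0.452,
                       effect_scale = 1,
                       h2_bg = c(BW = 0.08, BD = 0.08, CN = 0.05),
                       fg = c(BW = 0.62, BD = 0.62, CN = 0.84),
                       trait_means = c(BW = 21.0, BD = 41.2, CN = 12.7),
                       trait_sds = c(BW = 7.4, BD = 6.7, CN = 4.9),
                       trait_cors = c(BW_BD = 0.92, BD_CN = 0.36,
                                      BW_CN = 0.23),
                       ld_pair = 0.85, ld_triple = 0.65,
                       lnc_fraction = 0.05,
                       n_go_terms = 30, go_enriched_frac = 0.8,
                       n_null_pairs = 20, seed = 1) {
  cfg <- as.list(environment())
  if (any(cfg$fg < 0 | cfg$fg > 1) || any(cfg$h2_bg < 0 | cfg$h2_bg > 1) ||
      any(cfg$fg * cfg$effect_scale^0 + cfg$h2_bg > 1))
    stop_tras("infeasible variance budget: fg + h2_bg must be <= 1 per trait")
  if (cfg$fst <= 0 || cfg$fst >= 1) stop_tras("fst must be in (0, 1)")
  if (cfg$n_transcripts < 20 || cfg$n_snps < 20)
    stop_tras("cohort too small for the planted architecture")
  structure(cfg, class = "sim_config")
}

# Balding-Nichols dosages: subpop frequencies Beta-distributed around an
# ancestral frequency, one diploid draw per accession.
bn_snp <- function(p0, fst, pop, n_subpops) {
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  pk <- stats::rbeta(n_subpops, a, b)
  pk <- pmin(pmax(pk, 0.01), 0.99)
  list(dosage = stats::rbinom(length(pop), 2, pk[pop]), pk = pk)
}

# LD copy of an existing dosage vector: per-accession copy mask at rate rho,
# fresh Balding-Nichols draws elsewhere (dosage correlation ~ rho).
ld_snp <- function(base, p0, fst, pop, n_subpops, rho) {
  fresh <- bn_snp(p0, fst, pop, n_subpops)
  m <- stats::rbinom(length(base), 1, rho)
  list(dosage = ifelse(m == 1, base, fresh$dosage), pk = fresh$pk)
}

# Nearest correlation matrix by eigenvalue flooring + diagonal rescale.
near_pd_corr <- function(R) {
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-6)
  R2 <- eg$vectors %*% diag(vals, length(vals)) %*% t(eg$vectors)
  d <- sqrt(diag(R2))
  R2 / tcrossprod(d)
}

#' Simulate a full cohort with planted truth
#'
#' Generates genotypes, expression, phenotypes, module labels, GO
#' annotation and the truth table; optionally writes everything through the
#' package's own writers (VCF + TSVs + JSON truth). Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, files
#'   `genotypes.vcf`, `expression.tsv`, `phenotypes.tsv`, `modules.tsv`,
#'   `go_annotation.tsv`, `truth.json` are written there.
#' @return list: `G` (genotype_matrix, pre-QC truth), `E`
#'   (expression_matrix, raw abundance), `P` (phenotype_table), `modules`
#'   (named vector), `go` (annotation data.frame), `truth` (list).
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_snps
  t_n <- config$n_transcripts
  es <- config$effect_scale
  pop <- rep(seq_len(config$n_subpops), length.out = n)
  samples <- sprintf("L%03d", seq_len(n))
  transcripts <- sprintf("TR%04d", seq_len(t_n))

  ## ---- special entities -------------------------------------------------
  # cascade (CN): B1 -> A1 (linked pair); B2, B3 -> A2 (linked triple)
  # BW/BD: direct SNP sdir (linked to Tp's cis SNP), mediated Tp (+), Tm (-)
  special_tr <- c(B1 = "TR0001", A1 = "TR0002", B2 = "TR0003",
                  B3 = "TR0004", A2 = "TR0005", DIRHOST = "TR0006",
                  TP = "TR0007", TM = "TR0008")
  ## ---- genotypes --------------------------------------------------------
  p0 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dos <- matrix(0L, n, m)
  pk_mat <- matrix(0, config$n_subpops, m)
  special_p0 <- stats::runif(8, 0.3, 0.7)
  # ordinary SNPs first
  for (j in seq_len(m)) {
    s <- bn_snp(p0[j], config$fst, pop, config$n_subpops)
    dos[, j] <- s$dosage
    pk_mat[, j] <- s$pk
  }
  # overwrite the first 8 columns with the planted, partially linked SNPs
  sp_idx <- 1:8
  names(sp_idx) <- c("sB1", "sA1", "sB2", "sB3", "sA2", "sdir", "sTp", "sTm")
  draw <- function(j, p) {
    s <- bn_snp(p, config$fst, pop, config$n_subpops)
    dos[, j] <<- s$dosage; pk_mat[, j] <<- s$pk; p0[j] <<- p
  }
  draw_ld <- function(j, base_j, p, rho) {
    s <- ld_snp(dos[, base_j], p, config$fst, pop, config$n_subpops, rho)
    dos[, j] <<- s$dosage; pk_mat[, j] <<- s$pk; p0[j] <<- p
  }
  draw(1, special_p0[1])                               # sB1
  draw_ld(2, 1, special_p0[2], config$ld_pair)         # sA1 ~ sB1
  draw(3, special_p0[3])                               # sB2
  draw_ld(4, 3, special_p0[4], config$ld_triple)       # sB3 ~ sB2
  draw_ld(5, 3, special_p0[5], config$ld_triple)       # sA2 ~ sB2
  draw(6, special_p0[6])                               # sdir
  draw_ld(7, 6, special_p0[7], 0.6)                    # sTp ~ sdir
  draw(8, special_p0[8])                               # sTm

  # anchor SNPs to transcripts: planted SNPs on their host transcripts,
  # the rest uniformly (several SNPs may share a transcript)
  host <- c(special_tr[c("B1", "A1", "B2", "B3", "A2", "DIRHOST",
                         "TP", "TM")],
            sample(transcripts, m - 8, replace = TRUE))
  position <- integer(m)
  for (tr in unique(host)) {
    jj <- which(host == tr)
    position[jj] <- sort(sample.int(1500, length(jj)))
  }
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                     transcript_id = unname(host), position = position,
                     ref_allele = unname(ref), alt_allele = unname(alt),
                     stringsAsFactors = FALSE)

  sz <- apply(dos[, sp_idx, drop = FALSE], 2, std_vec)
  colnames(sz) <- names(sp_idx)

  ## ---- polygenic background --------------------------------------------
  Zs <- apply(dos, 2, std_vec)
  u <- std_vec(drop(Zs %*% stats::rnorm(m)) / sqrt(m))

  ## ---- planted expression (latent, standardized scale) ------------------
  rn <- function() stats::rnorm(n)
  B1 <- es * sqrt(0.70) * sz[, "sB1"] + sqrt(0.30) * rn()
  B2 <- es * sqrt(0.70) * sz[, "sB2"] + sqrt(0.30) * rn()
  B3 <- es * sqrt(0.70) * sz[, "sB3"] + sqrt(0.30) * rn()
  A1 <- es * (sqrt(0.60) * B1 + sqrt(0.25) * sz[, "sA1"]) + sqrt(0.15) * rn()
  A2 <- es * (sqrt(0.27) * B2 + sqrt(0.27) * B3 +
                sqrt(0.32) * sz[, "sA2"]) + sqrt(0.14) * rn()
  TP <- es * sqrt(0.70) * sz[, "sTp"] + sqrt(0.30) * rn()
  TM <- es * sqrt(0.70) * sz[, "sTm"] + sqrt(0.30) * rn()
  DIRHOST <- rn()  # host of the direct SNP; expression itself unaffected

  ## ---- traits -----------------------------------------------------------
  g_cn <- 0.55 * A1 + 0.55 * A2 + 0.30 * B1 + 0.25 * B2 + 0.25 * B3 +
    0.46 * (sz[, "sB1"] + sz[, "sA1"]) + 0.42 * (sz[, "sB2"] + sz[, "sB3"]) +
    0.50 * sz[, "sA2"]
  g_bw <- 0.40 * sz[, "sdir"] + 0.42 * TP - 0.48 * TM +
    0.32 * std_vec(g_cn)
  zero <- rep(0, n)
  g <- cbind(BW = if (es > 0) std_vec(g_bw) else zero,
             BD = if (es > 0) std_vec(g_bw) else zero,
             CN = if (es > 0) std_vec(g_cn) else zero)
  fg <- if (es > 0) config$fg else c(BW = 0, BD = 0, CN = 0)
  h2 <- config$h2_bg
  # residual correlations solved from the targets given the realized
  # genetic covariances, then projected to the nearest correlation matrix
  rho_t <- matrix(c(1, config$trait_cors["BW_BD"], config$trait_cors["BW_CN"],
                    config$trait_cors["BW_BD"], 1, config$trait_cors["BD_CN"],
                    config$trait_cors["BW_CN"], config$trait_cors["BD_CN"], 1),
                  3, 3, dimnames = list(names(fg), names(fg)))
  vres <- pmax(1 - fg - h2, 1e-6)
  Re <- diag(3)
  for (i in 1:2) for (j in (i + 1):3) {
    covg <- sqrt(fg[i] * fg[j]) *
      (if (es > 0) stats::cor(g[, i], g[, j]) else 0)
    covu <- sqrt(h2[i] * h2[j])
    Re[i, j] <- Re[j, i] <-
      min(max((rho_t[i, j] - covg - covu) / sqrt(vres[i] * vres[j]),
              -0.97), 0.97)
  }
  Re <- near_pd_corr(Re)
  eps <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(Re)
  lat <- sapply(1:3, function(i)
    sqrt(fg[i]) * g[, i] + sqrt(h2[i]) * u + sqrt(vres[i]) * eps[, i])
  colnames(lat) <- names(fg)
  traits <- as.data.frame(sapply(names(fg), function(k) {
    v <- std_vec(lat[, k]) * config$trait_sds[k] + config$trait_means[k]
    pmax(v, 0.05 * config$trait_means[k])
  }))
  rownames(traits) <- samples

  ## ---- modules and background expression -------------------------------
  module_labels <- paste0("M", sprintf("%02d", seq_len(config$n_modules)))
  factors <- matrix(stats::rnorm(n * config$n_modules), n)
  r43 <- config$module_trait_r
  factors[, 1] <- r43 * std_vec(lat[, "CN"]) + sqrt(1 - r43^2) * rn()
  modules <- setNames(rep(NA_character_, t_n), transcripts)
  # cascade transcripts share the trait-coupled module (cf. a module
  # concentrating most CN-related transcripts); BW mediators go to module 2
  modules[special_tr[c("B1", "A1", "B2", "B3", "A2")]] <- module_labels[1]
  modules[special_tr[c("TP", "TM", "DIRHOST")]] <- module_labels[2]
  bg_tr <- setdiff(transcripts, special_tr)
  assigned <- sample(bg_tr, round(config$module_fraction * length(bg_tr)))
  modules[assigned] <- sample(module_labels, length(assigned), replace = TRUE)

  lam <- sqrt(config$module_snr / (config$module_snr + 1))
  zmat <- matrix(stats::rnorm(n * t_n), n, t_n,
                 dimnames = list(samples, transcripts))
  for (tr in assigned) {
    k <- match(modules[tr], module_labels)
    zmat[, tr] <- lam * factors[, k] + sqrt(1 - lam^2) * stats::rnorm(n)
  }
  # background cis effects: a fraction of transcripts that carry a SNP get
  # a planted cis effect from their first SNP
  with_snp <- setdiff(intersect(bg_tr, snps$transcript_id), assigned[0])
  with_snp <- setdiff(with_snp, special_tr)
  n_cis <- round(config$cis_fraction * length(with_snp))
  cis_tr <- if (n_cis > 0) sample(with_snp, n_cis) else character()
  cis_snp <- character()
  for (tr in cis_tr) {
    j <- which(snps$transcript_id == tr)[1]
    x <- std_vec(dos[, j])
    zmat[, tr] <- es * sqrt(config$cis_r2_bg) * x +
      sqrt(1 - config$cis_r2_bg) * std_vec(zmat[, tr])
    cis_snp <- c(cis_snp, snps$snp_id[j])
  }
  for (k in names(special_tr))
    zmat[, special_tr[k]] <- get(k)

  ## ---- abundance transform ---------------------------------------------
  loc <- stats::runif(t_n, 4, 8)
  expr <- sweep(sweep(zmat, 2, rep(1.2, t_n), "*"), 2, loc, "+")
  expr <- round(pmax(2^expr - 1, 0), 3)

  ## ---- genotype missingness --------------------------------------------
  dos_na <- dos
  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * n * m)
    idx <- sample.int(n * m, nmiss)
    dos_na[idx] <- NA
  }

  ## ---- lncRNA tags and GO annotation -----------------------------------
  lnc <- union(unname(special_tr[c("A1", "B2")]),
               sample(bg_tr, round(config$lnc_fraction * length(bg_tr))))
  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  term_name <- paste0("process_", seq_len(config$n_go_terms))
  # planted enrichment: module k's transcripts carry term k at high rate
  ann <- list()
  mod_term <- setNames(terms[seq_len(config$n_modules)], module_labels)
  for (tr in transcripts) {
    tms <- character()
    if (!is.na(modules[tr]) &&
        stats::runif(1) < config$go_enriched_frac)
      tms <- mod_term[[modules[tr]]]
    extra <- sample(terms, stats::rpois(1, 1) %% 3)
    tms <- unique(c(tms, extra))
    if (length(tms))
      ann[[tr]] <- data.frame(transcript_id = tr, term_id = tms,
                              term_name = term_name[match(tms, terms)],
                              stringsAsFactors = FALSE)
  }
  go <- do.call(rbind, ann)
  rownames(go) <- NULL

  ## ---- truth table ------------------------------------------------------
  sid <- snps$snp_id
  truth <- list(
    config = unclass(config),
    subpop = pop,
    subpop_freqs = pk_mat,
    ancestral_freqs = p0,
    special_snps = setNames(sid[sp_idx], names(sp_idx)),
    direct_snp = sid[6],  # the ~30%-variance direct causal SNP on BW/BD
    causal_snps = list(
      BW = sid[c(6, 7, 8)], BD = sid[c(6, 7, 8)], CN = sid[1:5]),
    causal_transcripts = list(
      BW = data.frame(transcript_id = unname(special_tr[c("TP", "TM")]),
                      sign = c("+", "-"), stringsAsFactors = FALSE),
      BD = data.frame(transcript_id = unname(special_tr[c("TP", "TM")]),
                      sign = c("+", "-"), stringsAsFactors = FALSE),
      CN = data.frame(
        transcript_id = unname(special_tr[c("B1", "A1", "B2", "B3", "A2")]),
        sign = rep("+", 5), stringsAsFactors = FALSE)),
    cascade_edges = data.frame(
      source_id = unname(special_tr[c("B1", "B2", "B3")]),
      target_id = unname(special_tr[c("A1", "A2", "A2")]),
      trait = "CN", stringsAsFactors = FALSE),
    cis_background = data.frame(transcript_id = cis_tr, snp_id = cis_snp,
                                stringsAsFactors = FALSE),
    null_pairs = {
      free <- setdiff(bg_tr, c(cis_tr, names(modules)[!is.na(modules)]))
      if (length(free) < 2 * config$n_null_pairs)
        free <- setdiff(bg_tr, cis_tr)
      npair <- min(config$n_null_pairs, floor(length(free) / 2))
      pr <- matrix(sample(free, 2 * npair), ncol = 2)
      data.frame(a = pr[, 1], b = pr[, 2], stringsAsFactors = FALSE)
    },
    modules = modules,
    trait_module = module_labels[1],
    module_terms = mod_term,
    lncrna_ids = lnc)

  G <- new_genotype_matrix(samples, snps, dos_na)
  E <- new_expression_matrix(samples, expr)
  P <- new_phenotype_table(samples, traits,
                           units = c(BW = "g", BD = "mm", CN = "count"))
  cohort <- list(G = G, E = E, P = P, modules = modules, go = go,
                 truth = truth)
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a simulated cohort through the pipeline's own writers
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_vcf(cohort$G, file.path(dir, "genotypes.vcf"))
  write_expression(cohort$E, file.path(dir, "expression.tsv"))
  write_phenotypes(cohort$P, file.path(dir, "phenotypes.tsv"))
  mods <- cohort$modules[!is.na(cohort$modules)]
  write_tsv_commented(data.frame(transcript_id = names(mods),
                                 module = unname(mods),
                                 stringsAsFactors = FALSE),
                      file.path(dir, "modules.tsv"))
  write_tsv_commented(cohort$go, file.path(dir, "go_annotation.tsv"))
  tr <- cohort$truth
  tr$subpop_freqs <- NULL  # bulky; regenerate from seed when needed
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' Score pipeline outputs against the planted truth
#'
#' Per-stage sensitivity and false-discovery counts: causal-SNP detection
#' at the Bonferroni and suggestive thresholds, trait-related-transcript
#' recall/precision and regulation-direction accuracy, cascade-edge
#' recall/precision, false edges among planted null pairs, and (when
#' enrichment results are supplied) planted-term recall.
#'
#' @param truth truth list from [simulate_cohort()].
#' @param results list with any of: `scans` (named per trait, each an
#'   [association_scan()] result), `thresholds` (a `threshold_set`),
#'   `trait_related` (stacked data.frame), `edges` (network edge table),
#'   `enrichment` (named list module -> [go_enrichment()] table).
#' @return list of per-stage score data.frames.
#' @export
evaluate_recovery <- function(truth, results) {
  out <- list()
  if (!is.null(results$scans)) {
    th <- results$thresholds
    out$snp_detection <- do.call(rbind, lapply(names(results$scans),
                                               function(tr) {
      res <- results$scans[[tr]]$results
      if (!all(truth$causal_snps[[tr]] %in% res$snp_id) &&
          length(truth$causal_snps[[tr]]))
        stop_tras("truth SNP ids missing from scan results for %s", tr)
      causal <- truth$causal_snps[[tr]]
      hit_b <- res$snp_id[res$p <= th$bonferroni_p]
      hit_s <- res$snp_id[res$p <= th$suggestive_p]
      data.frame(trait = tr, n_causal = length(causal),
                 detected_bonferroni = sum(causal %in% hit_b),
                 detected_suggestive = sum(causal %in% hit_s),
                 fp_bonferroni = sum(!hit_b %in% causal),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(results$trait_related)) {
    trt <- results$trait_related
    out$trait_related <- do.call(rbind, lapply(names(truth$causal_transcripts),
                                               function(tr) {
      tt <- truth$causal_transcripts[[tr]]
      called <- trt[trt$trait == tr, , drop = FALSE]
      i <- match(called$transcript_id, tt$transcript_id)
      planted_called <- called[!is.na(i), , drop = FALSE]
      data.frame(trait = tr, n_planted = nrow(tt), n_called = nrow(called),
                 n_planted_called = nrow(planted_called),
                 n_direction_correct = sum(planted_called$direction ==
                                             tt$sign[i[!is.na(i)]]),
                 n_false = nrow(called) - nrow(planted_called),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(results$edges)) {
    ed <- results$edges
    tkey <- paste(truth$cascade_edges$source_id, truth$cascade_edges$target_id)
    ekey <- paste(ed$source_id, ed$target_id)
    np <- truth$null_pairs
    nullkey <- c(paste(np$a, np$b), paste(np$b, np$a))
    out$network <- data.frame(
      n_planted_edges = length(tkey),
      n_recovered = sum(tkey %in% ekey),
      n_edges_called = length(ekey),
      n_false_among_null_pairs = sum(ekey %in% nullkey))
  }
  if (!is.null(results$enrichment)) {
    out$enrichment <- do.call(rbind, lapply(names(results$enrichment),
                                            function(mod) {
      planted <- truth$module_terms[[mod]]
      enr <- results$enrichment[[mod]]
      data.frame(module = mod, planted_term = planted,
                 recovered = planted %in% enr$term_id,
                 rank_of_planted = if (planted %in% enr$term_id)
                   which(enr$term_id == planted) else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  }
  out
}
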