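## IO layer: every external table the pipeline touches is read and written
## here, with strict validation, so downstream modules see clean in-memory
## objects only.
##
## Containers are light S3 lists:
##   genotype_matrix : samples, snps (data.frame), dosages (n x m, 0/1/2/NA)
##   expression_matrix: samples, transcripts, values (n x t), transformed
##   phenotype_table : samples, traits (data.frame of numeric columns), units

new_genotype_matrix <- function(samples, snps, dosages, qc = list()) {
  stopifnot(nrow(dosages) == length(samples), ncol(dosages) == nrow(snps))
  rownames(dosages) <- samples
  colnames(dosages) <- snps$snp_id
  structure(list(samples = samples, snps = snps, dosages = dosages, qc = qc),
            class = "genotype_matrix")
}

new_expression_matrix <- function(samples, values, transformed = FALSE) {
  structure(list(samples = samples, transcripts = colnames(values),
                 values = values, transformed = transformed),
            class = "expression_matrix")
}

new_phenotype_table <- function(samples, traits, units = NULL) {
  structure(list(samples = samples, traits = traits,
                 units = units %||% setNames(rep("", ncol(traits)),
                                             colnames(traits))),
            class = "phenotype_table")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d transcripts\n",
              length(x$samples), nrow(x$snps),
              length(unique(x$snps$transcript_id))))
  if (length(x$qc))
    cat(sprintf("  QC: %d monomorphic, %d low-MAF, %d high-missing removed\n",
                x$qc$n_monomorphic, x$qc$n_low_maf, x$qc$n_high_missing))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d transcripts (%s scale)\n",
              length(x$samples), length(x$transcripts),
              if (x$transformed) "log2(x+1)" else "raw"))
  invisible(x)
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d samples, traits: %s\n",
              length(x$samples), paste(colnames(x$traits), collapse = ", ")))
  invisible(x)
}

#' Read genotypes from a transcriptome-anchored VCF
#'
#' The VCF CHROM column holds a transcript identifier and POS a 1-based
#' position within that transcript, mirroring SNPs called against a de novo
#' transcriptome reference rather than a genome. Only biallelic SNP records
#' are used; multi-allelic records are skipped with a warning. Dosages count
#' alternate alleles (0/1/2); heterozygotes are kept as 1 with no
#' Hardy-Weinberg filtering, since the intended populations are clonal.
#'
#' QC removes, in order: SNPs with missing fraction above
#' `missing_ceiling`, monomorphic SNPs, and SNPs with minor-allele frequency
#' below `maf_floor`. Removal counts are kept in the `qc` field.
#'
#' @param path VCF 4.x file.
#' @param maf_floor minor-allele-frequency floor in \[0, 0.5\] (default 0.05).
#' @param missing_ceiling maximum per-SNP missing fraction (default 0.2).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, maf_floor = 0.05, missing_ceiling = 0.2) {
  stopifnot(maf_floor >= 0, maf_floor <= 0.5,
            missing_ceiling >= 0, missing_ceiling <= 1)
  if (!file.exists(path)) stop_tras("VCF not found: %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_tras("malformed VCF '%s': %s",
                                              path, conditionMessage(e)))
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- matrix(fixm, nrow = 1,
                                         dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop_tras("VCF '%s' contains no variant records", path)
  ok_bial <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (any(!ok_bial))
    warning(sprintf("%d multi-allelic/non-SNP record(s) skipped", sum(!ok_bial)))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[ok_bial, , drop = FALSE]
  fix <- fix[ok_bial, , drop = FALSE]
  if (nrow(fix) == 0) stop_tras("no biallelic SNPs in '%s'", path)

  # allele-dosage coding from GT strings; anything not 0/1 genotype is NA
  dose1 <- function(g) {
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    vapply(al, function(a) {
      if (length(a) != 2 || any(a == ".")) return(NA_real_)
      sum(as.numeric(a))
    }, numeric(1))
  }
  dosages <- t(apply(gt, 1, dose1))
  dosages <- matrix(as.numeric(dosages), nrow = nrow(gt),
                    dimnames = dimnames(gt))
  dosages <- t(dosages)  # samples x snps

  snp_id <- fix$ID
  snp_id[is.na(snp_id) | snp_id == "."] <-
    paste0(fix$CHROM, "_", fix$POS)[is.na(snp_id) | snp_id == "."]
  if (anyDuplicated(snp_id)) stop_tras("duplicate SNP ids in '%s'", path)
  snps <- data.frame(snp_id = snp_id, transcript_id = fix$CHROM,
                     position = as.integer(fix$POS),
                     ref_allele = fix$REF, alt_allele = fix$ALT,
                     stringsAsFactors = FALSE)
  if (anyDuplicated(snps[, c("transcript_id", "position")]))
    stop_tras("duplicate (transcript, position) in '%s'", path)
  if (any(snps$ref_allele == snps$alt_allele))
    stop_tras("REF == ALT for some record in '%s'", path)

  miss <- colMeans(is.na(dosages))
  keep_miss <- miss <= missing_ceiling
  nd <- apply(dosages, 2, function(x) length(unique(x[!is.na(x)])))
  keep_poly <- nd >= 2
  af <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep_maf <- maf >= maf_floor
  keep <- keep_miss & keep_poly & keep_maf
  qc <- list(n_input = nrow(snps),
             n_high_missing = sum(!keep_miss),
             n_monomorphic = sum(keep_miss & !keep_poly),
             n_low_maf = sum(keep_miss & keep_poly & !keep_maf),
             n_kept = sum(keep))
  if (!any(keep)) stop_tras("no SNPs survive QC in '%s'", path)
  new_genotype_matrix(colnames(gt), snps[keep, , drop = FALSE],
                      dosages[, keep, drop = FALSE], qc = qc)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Inverse of [read_genotypes()] (before QC): dosage 0/1/2 becomes
#' `0/0`, `0/1`, `1/1`; missing becomes `./.`.
#'
#' @param G a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=tras_%s", utils::packageVersion("tras")),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$samples), collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(G$snps)), function(j) {
    d <- G$dosages[, j]
    gt <- ifelse(is.na(d), "./.", code[d + 1])
    paste(c(G$snps$transcript_id[j], G$snps$position[j], G$snps$snp_id[j],
            G$snps$ref_allele[j], G$snps$alt_allele[j], ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read an expression matrix (samples x transcripts TSV)
#'
#' @param path TSV with a header row of transcript ids and sample ids in
#'   the first column.
#' @param log_transform if TRUE, values become `log2(x + 1)` and the
#'   `transformed` flag is set; all correlation and eQTL computations in the
#'   pipeline are intended to run on this scale.
#' @return an `expression_matrix`.
#' @export
read_expression <- function(path, log_transform = FALSE) {
  df <- read_tsv_plain(path)
  samples <- as.character(df[[1]])
  if (anyDuplicated(samples)) stop_tras("duplicate sample ids in '%s'", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1] + 1L
    stop_tras("non-numeric expression values in '%s' (column %d: %s)",
              path, bad, colnames(df)[bad])
  }
  if (any(!is.finite(m)))
    stop_tras("non-finite expression values in '%s'", path)
  if (any(m < 0)) {
    ij <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_tras("negative expression value at sample '%s', transcript '%s'",
              samples[ij[1]], colnames(m)[ij[2]])
  }
  rownames(m) <- samples
  if (log_transform) m <- log2(m + 1)
  new_expression_matrix(samples, m, transformed = log_transform)
}

#' Write an expression matrix as TSV
#' @param E an `expression_matrix` (written on its current scale).
#' @param path output file.
#' @export
write_expression <- function(E, path) {
  df <- data.frame(sample = E$samples, E$values, check.names = FALSE)
  write_tsv_commented(df, path, list(transformed = E$transformed))
}

#' Read a phenotype table (sample id + named trait columns)
#'
#' `NA` and empty cells become missing values.
#'
#' @param path TSV file.
#' @param units optional named character vector of trait units
#'   (e.g. `c(BW = "g", BD = "mm", CN = "count")`).
#' @return a `phenotype_table`.
#' @export
read_phenotypes <- function(path, units = NULL) {
  df <- read_tsv_plain(path, na.strings = c("NA", ""))
  samples <- as.character(df[[1]])
  if (anyDuplicated(samples))
    stop_tras("duplicate sample id in '%s': %s", path,
              samples[duplicated(samples)][1])
  traits <- df[, -1, drop = FALSE]
  for (k in colnames(traits)) {
    traits[[k]] <- as.numeric(traits[[k]])
    if (sum(!is.na(traits[[k]])) < 3)
      stop_tras("trait '%s' has fewer than 3 non-missing values", k)
  }
  rownames(traits) <- samples
  new_phenotype_table(samples, traits, units = units)
}

#' Write a phenotype table as TSV
#' @param P a `phenotype_table`.
#' @param path output file.
#' @export
write_phenotypes <- function(P, path) {
  df <- data.frame(sample = P$samples, P$traits, check.names = FALSE)
  write_tsv_commented(df, path)
}

#' Read module assignments (transcript_id, module columns)
#' @param path TSV file with columns `transcript_id` and `module`.
#' @return named character vector transcript_id -> module label.
#' @export
read_modules <- function(path) {
  df <- read_tsv_plain(path)
  stopifnot(all(c("transcript_id", "module") %in% colnames(df)))
  setNames(as.character(df$module), df$transcript_id)
}

#' Read a GO annotation table (GAF-lite: transcript_id, term_id, term_name)
#' @param path TSV file.
#' @return data frame with columns transcript_id, term_id, term_name.
#' @export
read_go_annotation <- function(path) {
  df <- read_tsv_plain(path)
  stopifnot(all(c("transcript_id", "term_id") %in% colnames(df)))
  if (is.null(df$term_name)) df$term_name <- df$term_id
  df[, c("transcript_id", "term_id", "term_name")]
}

#' Intersect and align samples across genotype, expression and phenotype data
#'
#' The intersection is computed once and applied identically regardless of
#' the input file ordering; all three objects are returned subset and
#' re-ordered to the same sample vector (genotype order wins).
#'
#' @param G a `genotype_matrix`.
#' @param E an `expression_matrix`.
#' @param P a `phenotype_table`.
#' @return list with aligned `G`, `E`, `P` and the common `samples`.
#' @export
align_samples <- function(G, E, P) {
  common <- intersect(intersect(G$samples, E$samples), P$samples)
  if (length(common) == 0) stop_tras("no samples shared across inputs")
  common <- G$samples[G$samples %in% common]  # deterministic order
  gi <- match(common, G$samples)
  G2 <- new_genotype_matrix(common, G$snps,
                            G$dosages[gi, , drop = FALSE], qc = G$qc)
  E2 <- new_expression_matrix(common,
                              E$values[match(common, E$samples), , drop = FALSE],
                              transformed = E$transformed)
  P2 <- new_phenotype_table(common,
                            P$traits[match(common, P$samples), , drop = FALSE],
                            units = P$units)
  list(G = G2, E = E2, P = P2, samples = common)
}

#' Mean-impute missing dosages per SNP
#'
#' Applied after QC and before any matrix algebra (kinship, PCA, scans).
#'
#' @param G a `genotype_matrix`.
#' @return a `genotype_matrix` with no missing dosages.
#' @export
impute_genotypes <- function(G) {
  d <- G$dosages
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  new_genotype_matrix(G$samples, G$snps, d, qc = G$qc)
}
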