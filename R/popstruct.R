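## Population-structure corrections for the mixed-model scans: kinship,
## principal-component covariates, and the study-wide significance
## thresholds derived from the (effective) number of markers.

#' Genomic kinship matrix
#'
#' `centered` is the VanRaden estimator K = Z Z' / sum_j 2 p_j (1 - p_j)
#' with Z the column-centered dosage matrix; `standardized` additionally
#' scales each column to unit variance and divides by the marker count.
#' Both keep the mean diagonal near 1. A ridge of 1e-6 I is added when the
#' smallest eigenvalue falls below 1e-8, so K is usable as a covariance.
#'
#' @param G an imputed `genotype_matrix` (no missing dosages).
#' @param estimator `"centered"` (default) or `"standardized"`.
#' @return a `kinship_matrix` (list: samples, K, estimator).
#' @export
compute_kinship <- function(G, estimator = c("centered", "standardized")) {
  estimator <- match.arg(estimator)
  d <- G$dosages
  if (anyNA(d)) stop_tras("compute_kinship requires imputed genotypes")
  p <- colMeans(d) / 2
  Z <- sweep(d, 2, 2 * p)
  if (estimator == "centered") {
    denom <- sum(2 * p * (1 - p))
    if (denom <= 0) stop_tras("all markers monomorphic")
    K <- tcrossprod(Z) / denom
  } else {
    s <- apply(d, 2, stats::sd)
    if (any(s == 0)) stop_tras("zero-variance marker under standardized estimator")
    Z <- sweep(Z, 2, s, "/")
    K <- tcrossprod(Z) / ncol(Z)
  }
  K <- (K + t(K)) / 2
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ridged <- FALSE
  if (ev_min < 1e-8) {
    K <- K + diag(1e-6, nrow(K))
    ridged <- TRUE
  }
  dimnames(K) <- list(G$samples, G$samples)
  structure(list(samples = G$samples, K = K, estimator = estimator,
                 ridged = ridged, min_eigenvalue = ev_min),
            class = "kinship_matrix")
}

#' Principal-component covariates for stratification correction
#'
#' Scores are left singular vectors of the column-centered dosage matrix
#' scaled by their singular values. The returned matrix W has an intercept
#' first column followed by `n_pcs` score columns (the association model's
#' fixed-effect design). Sign convention: each PC's largest-magnitude
#' loading is positive, so results are deterministic across platforms.
#'
#' @param G an imputed `genotype_matrix`.
#' @param n_pcs number of PCs (default 3).
#' @return a `covariate_set` (list: samples, W, pcs, var_explained).
#' @export
compute_pcs <- function(G, n_pcs = 3) {
  d <- G$dosages
  if (anyNA(d)) stop_tras("compute_pcs requires imputed genotypes")
  n <- nrow(d)
  if (n_pcs < 1 || n_pcs >= n) stop_tras("n_pcs must be in [1, n-1]")
  Z <- sweep(d, 2, colMeans(d))
  sv <- svd(Z, nu = n_pcs, nv = n_pcs)
  # deterministic sign: largest-|loading| entry of each right vector positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  W <- cbind(intercept = 1, scores)
  colnames(W) <- c("intercept", paste0("PC", seq_len(n_pcs)))
  rownames(W) <- G$samples
  if (qr(W)$rank < ncol(W)) stop_tras("covariate matrix is rank-deficient")
  structure(list(samples = G$samples, W = W, n_pcs = n_pcs,
                 var_explained = sv$d[seq_len(n_pcs)]^2 / sum(sv$d^2)),
            class = "covariate_set")
}

#' Effective number of independent markers (Li-Ji style)
#'
#' Eigenvalues lambda_i of the marker-marker correlation matrix contribute
#' I(lambda_i >= 1) + (lambda_i - floor(lambda_i)); their sum is the
#' effective test count used for Bonferroni correction. When m exceeds
#' `block_size` the computation runs on blocks of consecutive markers and
#' sums the per-block estimates, mirroring per-chromosome practice.
#'
#' @param G an imputed `genotype_matrix` with >= 2 markers.
#' @param block_size markers per eigendecomposition block (default 1000).
#' @return the effective marker count (numeric scalar).
#' @export
effective_marker_count <- function(G, block_size = 1000) {
  d <- G$dosages
  if (anyNA(d)) stop_tras("effective_marker_count requires imputed genotypes")
  m <- ncol(d)
  if (m < 2) stop_tras("need at least 2 markers")
  if (any(apply(d, 2, stats::sd) == 0))
    stop_tras("constant marker column; run QC first")
  blocks <- split(seq_len(m), ceiling(seq_len(m) / block_size))
  sum(vapply(blocks, function(idx) {
    if (length(idx) == 1) return(1)
    R <- stats::cor(d[, idx, drop = FALSE])
    lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    sum((lam >= 1) + (lam - floor(lam)))
  }, numeric(1)))
}

#' Study-wide significance thresholds
#'
#' Bonferroni per-test threshold alpha / m_eff plus the suggestive 1/N
#' threshold. With all markers treated as independent (m_eff = m_total =
#' 19,912) at alpha = 0.05 these give 2.5e-6 and 5e-5, the conventional
#' transcriptome-wide cutoffs for a panel of that size.
#'
#' @param m_total total marker count N.
#' @param m_eff effective marker count (defaults to `m_total`).
#' @param alpha study-wide significance level (default 0.05).
#' @return a `threshold_set` (list: m_total, m_eff, alpha, bonferroni_p,
#'   suggestive_p).
#' @export
significance_thresholds <- function(m_total, m_eff = m_total, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, m_total >= 1, m_eff >= 1)
  ts <- list(m_total = m_total, m_eff = m_eff, alpha = alpha,
             bonferroni_p = alpha / m_eff,
             suggestive_p = 1 / m_total)
  stopifnot(ts$bonferroni_p <= alpha, ts$suggestive_p <= 1)
  structure(ts, class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("thresholds: m_total=%d m_eff=%.1f alpha=%g -> bonferroni=%.3g suggestive=%.3g\n",
              x$m_total, x$m_eff, x$alpha, x$bonferroni_p, x$suggestive_p))
  invisible(x)
}

#' Write a square matrix (kinship, PC scores) as a TSV with row names
#' @param M matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(M, path) {
  df <- data.frame(sample = rownames(M), M, check.names = FALSE)
  write_tsv_commented(df, path)
}
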