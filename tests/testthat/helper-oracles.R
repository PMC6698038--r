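# Independent dense-matrix oracles for the mixed-model engine, written
# against the model definition only (explicit covariance inversion, no
# eigendecomposition shortcut shared with the implementation).

# Restricted log-likelihood profiled over sigma_g^2 at a given delta:
# y ~ N(W a, sigma_g^2 (K + delta I)).
dense_reml_loglik <- function(delta, y, W, K) {
  n <- length(y)
  c <- ncol(W)
  V <- K + delta * diag(n)
  Vi <- solve(V)
  WVW <- t(W) %*% Vi %*% W
  beta <- solve(WVW, t(W) %*% Vi %*% y)
  r <- y - W %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  np <- n - c
  as.numeric(0.5 * (np * log(np / (2 * pi)) - np - np * log(rss) -
                      determinant(V)$modulus - determinant(WVW)$modulus +
                      determinant(t(W) %*% W)$modulus))
}

# GLS effect and standard error of x given covariates W at fixed delta,
# with explicit inversion of (K + delta I).
dense_gls_marker <- function(delta, y, W, K, x) {
  n <- length(y)
  X <- cbind(W, x)
  Vi <- solve(K + delta * diag(n))
  XVX <- t(X) %*% Vi %*% X
  beta <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- drop(t(r) %*% Vi %*% r) / df
  cov <- sigma2 * solve(XVX)
  b <- beta[ncol(X)]
  se <- sqrt(cov[ncol(X), ncol(X)])
  list(beta = b, se = se,
       p = stats::pf((b / se)^2, 1, df, lower.tail = FALSE))
}

# Random small mixed-model instance with a valid kinship-like covariance.
random_lmm_instance <- function(n = 8, c = 2, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  K <- tcrossprod(A) / n
  K <- K / mean(diag(K))
  W <- cbind(1, matrix(rnorm(n * (c - 1)), n))
  L <- chol(K + 0.5 * diag(n))
  y <- drop(W %*% rnorm(c) + t(L) %*% rnorm(n))
  x <- rnorm(n)
  list(y = y, W = W, K = K, x = x)
}

# Small deterministic genotype container for unit tests.
toy_genotypes <- function(dosages, transcripts = NULL) {
  m <- ncol(dosages)
  n <- nrow(dosages)
  snps <- data.frame(
    snp_id = sprintf("s%03d", seq_len(m)),
    transcript_id = transcripts %||% sprintf("T%03d", seq_len(m)),
    position = seq_len(m) * 10L,
    ref_allele = "A", alt_allele = "G", stringsAsFactors = FALSE)
  tras:::new_genotype_matrix(sprintf("i%02d", seq_len(n)), snps, dosages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
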