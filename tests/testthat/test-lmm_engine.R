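test_that("REML fit matches the dense-matrix profile likelihood", {
  for (s in 1:12) {
    inst <- random_lmm_instance(n = sample(6:10, 1), c = 2, seed = s)
    fit <- fit_null(inst$y, inst$W, inst$K)
    # value agreement at the maximizer, via the independent dense formula
    expect_equal(fit$reml_loglik,
                 dense_reml_loglik(fit$delta, inst$y, inst$W, inst$K),
                 tolerance = 1e-6)
    # no grid point of the dense profile beats the returned maximum
    grid <- 10^seq(-5, 5, length.out = 400)
    dense <- vapply(grid, dense_reml_loglik, numeric(1),
                    y = inst$y, W = inst$W, K = inst$K)
    expect_gte(fit$reml_loglik, max(dense) - 1e-6)
  }
})

test_that("toy instance agrees with a dense two-stage grid search", {
  inst <- random_lmm_instance(n = 8, c = 2, seed = 99)
  fit <- fit_null(inst$y, inst$W, inst$K)
  # two-stage dense search with the explicit-inverse formula: coarse pass
  # over the whole delta range, then a fine grid around its optimum
  coarse <- vapply(10^seq(-5, 5, length.out = 2000), dense_reml_loglik,
                   numeric(1), y = inst$y, W = inst$W, K = inst$K)
  lg_best <- seq(-5, 5, length.out = 2000)[which.max(coarse)]
  fine_grid <- 10^seq(lg_best - 0.01, lg_best + 0.01, length.out = 4000)
  fine <- vapply(fine_grid, dense_reml_loglik, numeric(1),
                 y = inst$y, W = inst$W, K = inst$K)
  expect_equal(fit$reml_loglik, max(fine), tolerance = 1e-6)
})

test_that("marker effect and se match explicit GLS inversion", {
  for (s in 1:10) {
    inst <- random_lmm_instance(n = 8, c = 2, seed = 100 + s)
    fit <- fit_null(inst$y, inst$W, inst$K)
    got <- score_marker(fit, inst$x)
    want <- dense_gls_marker(fit$delta, inst$y, inst$W, inst$K, inst$x)
    expect_equal(got$beta, want$beta, tolerance = 1e-8)
    expect_equal(got$se, want$se, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
})

test_that("with K = I the scan reduces to ordinary least squares", {
  for (s in 1:20) {
    set.seed(2000 + s)
    n <- 30
    W <- cbind(1, rnorm(n))
    y <- rnorm(n)
    X <- matrix(rbinom(n * 5, 2, 0.4), n)
    G <- toy_genotypes(X)
    scan <- association_scan(y, W, diag(n), G)
    for (j in 1:5) {
      ols <- summary(lm(y ~ W[, 2] + X[, j]))$coefficients
      row <- scan$results[scan$results$snp_id == sprintf("s%03d", j), ]
      expect_equal(row$p, ols["X[, j]", "Pr(>|t|)"], tolerance = 1e-8)
      expect_equal(row$beta, ols["X[, j]", "Estimate"], tolerance = 1e-8)
    }
  }
})

test_that("pure-noise phenotype drives the variance ratio to the bound", {
  set.seed(5)
  n <- 40
  # strongly structured kinship (clonal groups); y carries none of it
  grp <- rep(1:4, each = 10)
  K <- 0.9 * outer(grp, grp, "==") + 0.1 * diag(n)
  deltas <- replicate(10, fit_null(rnorm(n), cbind(rep(1, n)), K)$delta)
  expect_gt(median(deltas), 1e3)
  expect_error(fit_null(rep(1, n), cbind(rep(1, n)), K), "no variance")
})

test_that("orthogonal and collinear markers are handled without aborting", {
  set.seed(6)
  n <- 24
  W <- cbind(rep(1, n))
  y <- rnorm(n)
  fit <- fit_null(y, W, diag(n))
  # marker orthogonal to the (here unrotated) residuals: beta = 0, p = 1
  r <- resid(lm(y ~ 1))
  x <- rnorm(n)
  x <- resid(lm(x ~ r)) # orthogonal to residuals and (approx) intercept
  x <- x - mean(x)
  got <- score_marker(fit, x)
  expect_equal(got$beta, 0, tolerance = 1e-10)
  expect_equal(got$p, 1, tolerance = 1e-10)
  # collinear with the intercept: degeneracy flag, not an exception
  got2 <- score_marker(fit, rep(2, n))
  expect_true(got2$degenerate)
  expect_equal(got2$p, 1)
})

test_that("scan is scale-equivariant and permutation-invariant", {
  coh <- simulate_cohort(sim_config(n_samples = 30, n_snps = 60,
                                    n_transcripts = 25, seed = 13,
                                    missing_rate = 0))
  G <- impute_genotypes(tras:::qc_genotypes(coh$G, 0.05, 0.2))
  K <- compute_kinship(G)
  W <- compute_pcs(G, 2)
  y <- coh$P$traits$BW
  s1 <- association_scan(y, W, K, G)
  s2 <- association_scan(1000 * y, W, K, G)
  expect_equal(s2$results$beta, 1000 * s1$results$beta, tolerance = 1e-10)
  expect_equal(s2$results$se, 1000 * s1$results$se, tolerance = 1e-10)
  expect_equal(s2$results$p, s1$results$p, tolerance = 1e-10)
  set.seed(1)
  ip <- sample(30)
  Gp <- tras:::new_genotype_matrix(G$samples[ip], G$snps, G$dosages[ip, ])
  s3 <- association_scan(y[ip], W$W[ip, ], K$K[ip, ip], Gp)
  expect_equal(s3$results$p, s1$results$p, tolerance = 1e-8)
})

test_that("exact per-marker delta re-optimization stays close to EMMAX", {
  coh <- simulate_cohort(sim_config(n_samples = 25, n_snps = 20,
                                    n_transcripts = 25, seed = 17,
                                    missing_rate = 0))
  G <- impute_genotypes(tras:::qc_genotypes(coh$G, 0.05, 0.2))
  K <- compute_kinship(G)
  y <- coh$P$traits$CN
  W <- cbind(rep(1, 25))
  fast <- association_scan(y, W, K, G)
  exact <- association_scan(y, W, K, G, exact_per_marker = TRUE)
  i <- match(fast$results$snp_id, exact$results$snp_id)
  expect_equal(cor(log10(fast$results$p), log10(exact$results$p[i])), 1,
               tolerance = 0.02)
})

test_that("REML recovers a known variance ratio at cohort scale", {
  set.seed(31)
  n <- 102
  A <- matrix(rnorm(n * 300), n)
  K <- tcrossprod(scale(A)) / 300
  eg <- eigen(K, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  W <- cbind(rep(1, n))
  deltas <- replicate(60, {
    y <- drop(L %*% rnorm(n)) + rnorm(n)  # true delta = 1
    fit_null(y, W, K)$delta
  })
  expect_gte(median(deltas), 0.5)
  expect_lte(median(deltas), 2)
})
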