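## Exact single-variance-component linear mixed model:
##   y = W a + x b + u + e,  u ~ N(0, sg2 K), e ~ N(0, se2 I), delta = se2/sg2.
## The kinship eigendecomposition K = U S U' rotates the model to
## independent errors with variances sg2 (S_i + delta); REML profiles out
## sg2 and the fixed effects, leaving a 1-D likelihood in delta that is
## maximized on a log grid and refined by scalar optimization. Markers are
## then scored by generalized least squares at the null delta (EMMAX-style)
## unless exact per-marker re-optimization is requested.

# Restricted profile log-likelihood in delta on rotated data.
# ystar, Wstar: U'y, U'W; S: kinship eigenvalues; ldWW: log det(W'W).
reml_profile_loglik <- function(delta, ystar, Wstar, S, ldWW) {
  n <- length(ystar)
  c <- ncol(Wstar)
  np <- n - c
  w <- 1 / (S + delta)
  sw <- sqrt(w)
  Xw <- Wstar * sw
  yw <- ystar * sw
  qx <- qr(Xw)
  rss <- sum(qr.resid(qx, yw)^2)
  if (!is.finite(rss) || rss <= 0) return(-Inf)
  ldXWX <- 2 * sum(log(abs(diag(qr.R(qx)))))
  0.5 * (np * log(np / (2 * pi)) - np - np * log(rss) -
           sum(log(S + delta)) - ldXWX + ldWW)
}

#' Fit the null mixed model (REML estimate of the variance ratio)
#'
#' Profiles the restricted likelihood over delta = sigma_e^2 / sigma_g^2 on
#' a log-spaced grid, brackets every sign change of the numerical
#' derivative, refines each bracket by scalar optimization to
#' |d log10(delta)| <= 1e-6, and returns the global maximizer together with
#' the kinship rotation, cached for reuse across markers.
#'
#' @param y phenotype vector (no missing values).
#' @param W fixed-effect design matrix (first column intercept), full rank.
#' @param K a `kinship_matrix` or bare symmetric matrix.
#' @param grid log-spaced delta grid (default 100 points in \[1e-5, 1e5\]).
#' @param refine refine grid maxima by scalar optimization (default TRUE).
#' @return a `null_fit` (list: delta, reml_loglik, sigma_g2, sigma_e2, U, S,
#'   h2 = sigma_g2 / (sigma_g2 + sigma_e2) on the rotated scale).
#' @export
fit_null <- function(y, W, K, grid = 10^seq(-5, 5, length.out = 100),
                     refine = TRUE) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  n <- length(y)
  stopifnot(nrow(W) == n, nrow(K) == n)
  if (stats::sd(y) == 0) stop_tras("phenotype has no variance")
  if (qr(W)$rank < ncol(W)) stop_tras("covariate matrix W is rank-deficient")
  if (n < ncol(W) + 2) stop_tras("too few samples for the model")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  U <- eg$vectors
  S <- pmax(eg$values, 0)
  ystar <- drop(crossprod(U, y))
  Wstar <- crossprod(U, W)
  ldWW <- as.numeric(determinant(crossprod(W), logarithm = TRUE)$modulus)
  ll <- vapply(grid, reml_profile_loglik, numeric(1),
               ystar = ystar, Wstar = Wstar, S = S, ldWW = ldWW)
  if (all(!is.finite(ll))) stop_tras("degenerate likelihood; phenotype unusable")
  best_i <- which.max(ll)
  delta_hat <- grid[best_i]
  best_ll <- ll[best_i]
  if (refine) {
    lg <- log10(grid)
    f <- function(ld) reml_profile_loglik(10^ld, ystar, Wstar, S, ldWW)
    # refine around every interior local maximum of the grid profile
    cand <- which(diff(sign(diff(ll))) < 0) + 1L
    cand <- union(cand, best_i)
    for (i in cand) {
      lo <- lg[max(1, i - 1)]
      hi <- lg[min(length(grid), i + 1)]
      op <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-7)
      if (op$objective > best_ll) {
        best_ll <- op$objective
        delta_hat <- 10^op$maximum
      }
    }
  }
  w <- 1 / (S + delta_hat)
  yw <- ystar * sqrt(w)
  Xw <- Wstar * sqrt(w)
  rss <- sum(qr.resid(qr(Xw), yw)^2)
  sg2 <- rss / (n - ncol(W))
  structure(list(delta = delta_hat, reml_loglik = best_ll,
                 sigma_g2 = sg2, sigma_e2 = sg2 * delta_hat,
                 h2 = 1 / (1 + delta_hat), U = U, S = S,
                 ystar = ystar, Wstar = Wstar),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("null_fit: delta=%.4g (h2=%.3f) REML loglik=%.4f\n",
              x$delta, x$h2, x$reml_loglik))
  invisible(x)
}

#' Score one marker against a fitted null model
#'
#' Generalized least squares of y on \[W x\] under covariance
#' sigma^2 (K + delta I), with delta fixed at the null estimate; the Wald
#' statistic (beta/se)^2 is referred to F(1, n - c - 1). A marker collinear
#' with the covariates yields p = 1 with a degeneracy flag rather than an
#' error, so scans never abort.
#'
#' @param fit a `null_fit`.
#' @param x dosage vector (imputed).
#' @param snp_id identifier carried into the result.
#' @return one-row data.frame: snp_id, beta, se, p, n_used, degenerate.
#' @export
score_marker <- function(fit, x, snp_id = "x") {
  res <- scan_rotated(fit, matrix(x, ncol = 1))
  data.frame(snp_id = snp_id, beta = res$beta, se = res$se, p = res$p,
             n_used = length(x), degenerate = res$degenerate,
             stringsAsFactors = FALSE)
}

# Vectorized GLS scoring of a dosage matrix against a null_fit.
scan_rotated <- function(fit, X) {
  n <- length(fit$ystar)
  c <- ncol(fit$Wstar)
  sw <- sqrt(1 / (fit$S + fit$delta))
  yw <- fit$ystar * sw
  Ww <- fit$Wstar * sw
  Xw <- (crossprod(fit$U, X)) * sw
  qw <- qr(Ww)
  ry <- qr.resid(qw, yw)
  RX <- qr.resid(qw, Xw)
  xtx <- colSums(RX^2)
  xty <- drop(crossprod(RX, ry))
  df <- n - c - 1
  degen <- xtx < max(1e-10, 1e-12 * n)
  beta <- ifelse(degen, 0, xty / xtx)
  rss <- pmax(sum(ry^2) - beta * xty, 0)
  sigma2 <- rss / df
  se <- ifelse(degen, NA_real_, sqrt(sigma2 / xtx))
  fstat <- ifelse(degen, 0, (beta / se)^2)
  p <- ifelse(degen, 1, stats::pf(fstat, 1, df, lower.tail = FALSE))
  list(beta = beta, se = se, p = p, fstat = fstat, degenerate = degen, df = df)
}

#' Mixed-model association scan over all markers
#'
#' Fits the null model once, then scores every SNP by GLS at the null delta
#' (EMMAX approximation); `exact_per_marker = TRUE` instead re-optimizes
#' delta for every marker with the marker in the design (exact test, much
#' slower). Samples with missing phenotype are dropped for the whole scan.
#' Results are sorted by p ascending with ties broken by snp_id.
#'
#' @param y named or sample-aligned phenotype vector (NAs dropped).
#' @param W covariate matrix from [compute_pcs()] (or any full-rank design).
#' @param K kinship from [compute_kinship()].
#' @param G an imputed `genotype_matrix`.
#' @param threshold_p significance threshold applied to the `significant`
#'   subset (default: none, returns all with an empty subset).
#' @param exact_per_marker re-optimize delta per marker (default FALSE).
#' @return list: `results` (data.frame snp_id, transcript_id, position,
#'   beta, se, p, n_used, degenerate), `significant` (subset with
#'   p <= threshold_p), `null_fit`.
#' @export
association_scan <- function(y, W, K, G, threshold_p = 0,
                             exact_per_marker = FALSE) {
  if (inherits(W, "covariate_set")) W <- W$W
  if (inherits(K, "kinship_matrix")) K <- K$K
  keep <- is.finite(y)
  if (sum(keep) < ncol(W) + 2) stop_tras("too few phenotyped samples")
  y <- y[keep]
  W <- W[keep, , drop = FALSE]
  K <- K[keep, keep, drop = FALSE]
  X <- G$dosages[keep, , drop = FALSE]
  fit <- fit_null(y, W, K)
  if (exact_per_marker) {
    sc <- lapply(seq_len(ncol(X)), function(j) {
      x <- X[, j]
      W2 <- cbind(W, x)
      if (qr(W2)$rank < ncol(W2)) {
        return(list(beta = 0, se = NA_real_, p = 1, degenerate = TRUE))
      }
      fj <- fit_null(y, W2, K)
      # delta from the marker-inclusive fit; score against W-only projection
      fj$Wstar <- crossprod(fj$U, W)
      r <- scan_rotated(fj, matrix(x, ncol = 1))
      list(beta = r$beta, se = r$se, p = r$p, degenerate = r$degenerate)
    })
    beta <- vapply(sc, `[[`, numeric(1), "beta")
    se <- vapply(sc, `[[`, numeric(1), "se")
    p <- vapply(sc, `[[`, numeric(1), "p")
    degen <- vapply(sc, `[[`, logical(1), "degenerate")
  } else {
    r <- scan_rotated(fit, X)
    beta <- r$beta; se <- r$se; p <- r$p; degen <- r$degenerate
  }
  res <- data.frame(snp_id = G$snps$snp_id,
                    transcript_id = G$snps$transcript_id,
                    position = G$snps$position,
                    beta = beta, se = se, p = p,
                    n_used = sum(keep), degenerate = degen,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$snp_id), ]
  rownames(res) <- NULL
  list(results = res,
       significant = res[res$p <= threshold_p, , drop = FALSE],
       null_fit = fit)
}

#' Write scan results as TSV
#' @param scan result of [association_scan()].
#' @param path output file.
#' @param params parameters echoed in the header.
#' @export
write_scan_tsv <- function(scan, path, params = list()) {
  write_tsv_commented(scan$results, path, params)
}
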