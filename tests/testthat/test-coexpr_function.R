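test_that("eigengene of duplicated transcripts is their common profile", {
  set.seed(21)
  n <- 40
  v <- rnorm(n)
  E <- tras:::new_expression_matrix(paste0("s", 1:n),
                                    cbind(T1 = v, T2 = v))
  mods <- c(T1 = "M1", T2 = "M1")
  eg <- module_eigengene(E, mods, "M1")
  z <- (v - mean(v)) / sd(v)
  expect_equal(abs(cor(eg, z)), 1, tolerance = 1e-10)
  expect_gt(cor(eg, z), 0)  # sign convention: tracks the module mean
  expect_equal(sum(eg^2), 1, tolerance = 1e-10)
  # singleton module: standardized vector itself, flagged
  eg1 <- module_eigengene(E, c(T1 = "Ms"), "Ms")
  expect_true(attr(eg1, "singleton"))
  expect_equal(abs(cor(eg1, v)), 1, tolerance = 1e-10)
})

test_that("eigengene recovers a latent factor and ignores column order", {
  set.seed(22)
  n <- 102
  f <- rnorm(n)
  snr <- 2
  X <- sapply(1:30, function(i)
    sqrt(snr / (snr + 1)) * f + sqrt(1 / (snr + 1)) * rnorm(n))
  colnames(X) <- paste0("T", 1:30)
  E <- tras:::new_expression_matrix(paste0("s", 1:n), pmax(X + 5, 0))
  mods <- setNames(rep("M1", 30), colnames(X))
  eg <- module_eigengene(E, mods, "M1")
  expect_gte(abs(cor(eg, f)), 0.9)
  perm <- sample(30)
  Ep <- tras:::new_expression_matrix(paste0("s", 1:n),
                                     pmax(X + 5, 0)[, perm])
  egp <- module_eigengene(Ep, mods, "M1")
  expect_equal(abs(cor(eg, egp)), 1, tolerance = 1e-8)
  # flipping the sign of every column leaves |trait correlation| unchanged
  Eneg <- tras:::new_expression_matrix(paste0("s", 1:n), pmax(-X + 5, 0))
  egn <- module_eigengene(Eneg, mods, "M1")
  y <- f + rnorm(n)
  expect_equal(abs(cor(eg, y)), abs(cor(egn, y)), tolerance = 0.02)
})

test_that("module-trait correlation flags real couplings, not permutations", {
  # recovery at the published-scale effect size r ~ 0.45, n = 102
  hits <- 0; close_r <- 0; n_seeds <- 25
  for (s in 1:n_seeds) {
    set.seed(s)
    n <- 102
    y <- rnorm(n)
    f <- 0.452 * scale(y)[, 1] + sqrt(1 - 0.452^2) * rnorm(n)
    X <- sapply(1:20, function(i) sqrt(2/3) * f + sqrt(1/3) * rnorm(n))
    colnames(X) <- paste0("T", 1:20)
    E <- tras:::new_expression_matrix(paste0("s", 1:n), pmax(X + 6, 0))
    mods <- setNames(rep("M1", 20), colnames(X))
    eg <- list(M1 = module_eigengene(E, mods, "M1"))
    P <- tras:::new_phenotype_table(paste0("s", 1:n), data.frame(CN = y))
    mt <- module_trait_correlation(eg, P)
    hits <- hits + mt$significant[1]
    close_r <- close_r + (abs(abs(mt$r[1]) - 0.452) <= 0.15)
  }
  expect_gte(hits / n_seeds, 0.8)
  expect_gte(close_r / n_seeds, 0.85)
  # permutation null: significance rate near alpha
  set.seed(1)
  n <- 102
  eg <- list(M1 = rnorm(n))
  sig <- replicate(200, {
    P <- tras:::new_phenotype_table(paste0("s", 1:n),
                                    data.frame(CN = sample(rnorm(n))))
    module_trait_correlation(eg, P)$significant[1]
  })
  expect_lt(abs(mean(sig) - 0.05), 0.04)
})

test_that("lncRNA partner sets follow module membership", {
  mods <- c(L1 = "M1", T1 = "M1", T2 = "M1", T3 = "M1", T4 = "M1",
            L2 = "M2", T5 = "M3")
  expect_setequal(lncrna_partners("L1", mods), c("T1", "T2", "T3", "T4"))
  expect_length(lncrna_partners("L2", mods), 0)
  expect_warning(p <- lncrna_partners("ZZ", mods), "no module")
  expect_length(p, 0)
  coh <- simulate_cohort(sim_config(n_samples = 20, n_snps = 40,
                                    n_transcripts = 60, seed = 31))
  mods2 <- coh$truth$modules[!is.na(coh$truth$modules)]
  id <- names(mods2)[1]
  expect_setequal(lncrna_partners(id, mods2),
                  setdiff(names(mods2)[mods2 == mods2[[id]]], id))
})

test_that("hypergeometric p matches the closed form and full enumeration", {
  bg <- paste0("t", 1:20)
  ann <- data.frame(transcript_id = paste0("t", 1:5), term_id = "GO:1",
                    term_name = "x", stringsAsFactors = FALSE)
  res <- go_enrichment(paste0("t", 1:5), bg, ann, keep_all = TRUE)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # enumeration oracle for N <= 25: tail sum of the counting formula
  for (case in list(c(N = 25, K = 7, n = 9, k = 3), c(18, 5, 6, 2),
                    c(12, 4, 4, 4))) {
    N <- unname(case[1]); K <- unname(case[2])
    n <- unname(case[3]); k <- unname(case[4])
    enum <- sum(sapply(k:min(K, n), function(j)
      choose(K, j) * choose(N - K, n - j))) / choose(N, n)
    bg2 <- paste0("g", 1:N)
    ann2 <- data.frame(transcript_id = paste0("g", 1:K), term_id = "GO:9",
                       term_name = "y", stringsAsFactors = FALSE)
    # target with exactly k annotated members
    tgt <- c(paste0("g", seq_len(k)),
             if (n > k) paste0("g", K + seq_len(n - k)))
    r2 <- go_enrichment(tgt, bg2, ann2, keep_all = TRUE)
    expect_equal(r2$p_value, enum, tolerance = 1e-12)
  }
})

test_that("BH q-values are monotone and term-order invariant", {
  set.seed(41)
  bg <- paste0("t", 1:60)
  ann <- do.call(rbind, lapply(1:8, function(i)
    data.frame(transcript_id = sample(bg, 10), term_id = paste0("GO:", i),
               term_name = paste0("f", i), stringsAsFactors = FALSE)))
  tgt <- sample(bg, 15)
  r <- go_enrichment(tgt, bg, ann, keep_all = TRUE)
  expect_true(all(diff(r$q_value[order(r$p_value)]) >= -1e-12))
  expect_true(all(r$q_value >= r$p_value - 1e-12))
  expect_true(all(r$k_in_set <= pmin(r$K_in_background, r$n_set)))
  r2 <- go_enrichment(tgt, bg, ann[sample(nrow(ann)), ], keep_all = TRUE)
  expect_equal(r, r2)
  expect_error(go_enrichment(c(tgt, "NOPE"), bg, ann), "subset")
})

test_that("planted enrichment ranks first; null targets calibrate", {
  first <- 0; n_seeds <- 10
  for (s in 1:n_seeds) {
    set.seed(50 + s)
    bg <- paste0("t", 1:200)
    ann <- do.call(rbind, lapply(1:10, function(i)
      data.frame(transcript_id = sample(bg, 20), term_id = sprintf("GO:%02d", i),
                 term_name = paste0("f", i), stringsAsFactors = FALSE)))
    term_members <- ann$transcript_id[ann$term_id == "GO:05"]
    tgt <- unique(c(sample(term_members, 16), sample(bg, 10)))
    r <- go_enrichment(tgt, bg, ann, keep_all = TRUE)
    first <- first + (r$term_id[1] == "GO:05" && r$q_value[1] < 0.05)
  }
  expect_gte(first / n_seeds, 0.9)
  # uniform random targets: ~5% of terms significant at raw p < 0.05
  # (terms large enough that hypergeometric discreteness is mild)
  set.seed(60)
  bg <- paste0("t", 1:500)
  fracs <- replicate(50, {
    ann <- do.call(rbind, lapply(1:20, function(i)
      data.frame(transcript_id = sample(bg, 60), term_id = sprintf("GO:%02d", i),
                 term_name = "f", stringsAsFactors = FALSE)))
    r <- go_enrichment(sample(bg, 100), bg, ann, keep_all = TRUE)
    mean(r$p_value < 0.05)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.03)
})
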