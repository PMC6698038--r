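test_that("phenotype summary reproduces fold-range and handles degeneracy", {
  P <- tras:::new_phenotype_table(
    paste0("s", 1:4),
    data.frame(CN = c(5.8, 35.3, 12, 20), FLAT = c(1, 1, 1, 1),
               NEG = c(-1, 2, 3, 4)))
  s <- summarize_phenotypes(P)
  cn <- s$per_trait[s$per_trait$trait == "CN", ]
  expect_equal(round(cn$fold_range, 1), 6.1)  # 35.3 / 5.8
  expect_equal(s$per_trait$sd[s$per_trait$trait == "FLAT"], 0)
  expect_true(all(s$correlations$degenerate[
    s$correlations$trait_a == "FLAT" | s$correlations$trait_b == "FLAT"]))
  # min <= 0 -> fold-range undefined, no error
  expect_true(is.na(s$per_trait$fold_range[s$per_trait$trait == "NEG"]))
})

test_that("summary matches direct recomputation on a simulated cohort", {
  coh <- simulate_cohort(sim_config(n_samples = 30, n_snps = 40,
                                    n_transcripts = 25, seed = 4))
  s <- summarize_phenotypes(coh$P)
  for (k in c("BW", "BD", "CN")) {
    x <- coh$P$traits[[k]]
    row <- s$per_trait[s$per_trait$trait == k, ]
    expect_equal(row$mean, mean(x))
    expect_equal(row$sd, sd(x))
    expect_equal(row$fold_range, max(x) / min(x))
  }
  r_bw_bd <- cor(coh$P$traits$BW, coh$P$traits$BD)
  expect_equal(s$correlations$r[s$correlations$trait_a == "BW" &
                                  s$correlations$trait_b == "BD"], r_bw_bd)
})

test_that("SNP-to-transcript mapping groups hits and rejects unknowns", {
  snps <- data.frame(snp_id = c("a", "b", "c", "d"),
                     transcript_id = c("T1", "T1", "T2", "T3"),
                     stringsAsFactors = FALSE)
  hits <- data.frame(snp_id = c("a", "b", "c"), p = c(1e-8, 1e-7, 1e-9),
                     stringsAsFactors = FALSE)
  mp <- map_snps_to_transcripts(hits, snps)
  expect_equal(sort(lengths(mp$mapping), decreasing = TRUE),
               c(T1 = 2L, T2 = 1L))
  expect_equal(mp$n_snps, 3L)
  expect_equal(mp$n_transcripts, 2L)
  expect_equal(map_snps_to_transcripts(hits[0, ], snps)$n_snps, 0L)
  expect_error(map_snps_to_transcripts(
    data.frame(snp_id = "zz"), snps), "unknown")
})

test_that("expression-trait correlation: exact and degenerate cases", {
  E <- tras:::new_expression_matrix(
    paste0("s", 1:5),
    cbind(T1 = c(2, 4, 6, 8, 10), T2 = c(1, 1, 1, 1, 1),
          T3 = c(5, 3, 8, 1, 9)))
  y <- 1:5
  r <- expression_trait_correlation(E, y, c("T1", "T2"))
  expect_equal(r$r[r$transcript_id == "T1"], 1)
  expect_lt(r$p[r$transcript_id == "T1"], 1e-10)
  expect_true(r$degenerate[r$transcript_id == "T2"])
  expect_equal(r$p[r$transcript_id == "T2"], 1)
  expect_error(expression_trait_correlation(E, y, "NOPE"), "not in")
})

test_that("trait-related calling is the two-filter intersection", {
  mapping <- list(mapping = list(T1 = c("a", "b"), T2 = "c", T3 = "d"),
                  n_snps = 4L, n_transcripts = 3L)
  correlations <- data.frame(
    transcript_id = c("T1", "T2", "T3"),
    r = c(0.8, -0.5, 0.1), p = c(0.001, 0.03, 0.8), n = 20,
    degenerate = FALSE, stringsAsFactors = FALSE)
  hits <- data.frame(snp_id = c("a", "b", "c", "d"),
                     p = c(1e-8, 1e-7, 1e-9, 1e-6), stringsAsFactors = FALSE)
  out <- call_trait_related(mapping, correlations, hits, "BW")
  expect_equal(out$transcript_id, c("T1", "T2"))
  expect_equal(out$direction, c("+", "-"))
  expect_equal(out$best_genotype_p, c(1e-8, 1e-9))
  # containment: trait-related transcripts are SNP-located transcripts
  expect_true(all(out$transcript_id %in% names(mapping$mapping)))
  # disjoint sets -> empty
  correlations$p <- 0.9
  expect_equal(nrow(call_trait_related(mapping, correlations, hits, "BW")), 0)
})

test_that("planted expression effects are recovered with correct direction", {
  hits <- 0; correct <- 0; called_planted <- 0
  for (s in 1:6) {
    coh <- simulate_cohort(sim_config(seed = 400 + s, n_snps = 400,
                                      n_transcripts = 120))
    out <- run_full_pipeline(coh)
    for (tr in c("BW", "CN")) {
      tt <- coh$truth$causal_transcripts[[tr]]
      called <- out$trait_related[out$trait_related$trait == tr, ]
      i <- match(called$transcript_id, tt$transcript_id)
      called_planted <- called_planted + sum(!is.na(i))
      correct <- correct + sum(called$direction[!is.na(i)] ==
                                 tt$sign[i[!is.na(i)]])
    }
    # per-trait count sanity: trait-related <= transcripts <= snps
    cnt <- out$manifest$counts
    expect_true(all(cnt$n_trait_related <= cnt$n_transcripts))
    expect_true(all(cnt$n_transcripts <= cnt$n_snps))
  }
  expect_gt(called_planted, 10)
  expect_gte(correct / called_planted, 0.9)
})

test_that("flipping a planted expression effect flips only the direction", {
  set.seed(77)
  n <- 60
  y <- rnorm(n)
  Ev <- cbind(T1 = y + rnorm(n, sd = 0.5))
  E <- tras:::new_expression_matrix(paste0("s", 1:n), Ev)
  Eneg <- tras:::new_expression_matrix(paste0("s", 1:n),
                                       cbind(T1 = max(Ev) - Ev[, 1]))
  mapping <- list(mapping = list(T1 = "a"), n_snps = 1L, n_transcripts = 1L)
  hits <- data.frame(snp_id = "a", p = 1e-9, stringsAsFactors = FALSE)
  c1 <- expression_trait_correlation(E, y, "T1")
  c2 <- expression_trait_correlation(Eneg, y, "T1")
  o1 <- call_trait_related(mapping, c1, hits, "BW")
  o2 <- call_trait_related(mapping, c2, hits, "BW")
  expect_equal(o1$direction, "+")
  expect_equal(o2$direction, "-")
  expect_equal(o1$expression_p, o2$expression_p, tolerance = 1e-12)
  expect_equal(o1$best_genotype_p, o2$best_genotype_p)
})
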