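# fixture: 2 clusters over 6 ligands, hits for two targets
assoc_fixture <- function() {
  d <- block_distmat(c(4, 2), within = 0.1, between = 0.9, seed = 2)
  cl <- hierarchical_cluster(d, "average", 0.5)  # C01 = L01..L04, C02 = L05,L06
  mk <- function(t, ids) structure(list(target_id = t, ligand_ids = ids),
                                   class = "top_hit_set")
  hits <- list(mk("T1", c("L01", "L02")),          # 2 of 4 in C01
               mk("T2", c("L05", "L06", "L01")))   # all of C02 + 1 in C01
  list(cl = cl, hits = hits)
}

test_that("Matrix 1 holds within-cluster hit fractions", {
  fx <- assoc_fixture()
  M1 <- build_matrix1(fx$hits, fx$cl)
  expect_equal(M1["C01", "T1"], 0.5)    # 2 hits / cluster of 4
  expect_equal(M1["C02", "T2"], 1.0)    # cluster fully made of T2 hits
  expect_equal(M1["C02", "T1"], 0.0)    # no hits for T1
  expect_true(all(M1 >= 0 & M1 <= 1))
  # unclustered hit errors
  bad <- c(fx$hits, list(structure(list(target_id = "T3", ligand_ids = "zz"),
                                   class = "top_hit_set")))
  expect_error(build_matrix1(bad, fx$cl), class = "consistency_error")
})

test_that("Matrix 2 columns partition each target's hits", {
  fx <- assoc_fixture()
  M2 <- build_matrix2(fx$hits, fx$cl)
  expect_equal(M2["C01", "T1"], 1.0)           # all T1 hits in C01
  expect_equal(M2["C01", "T2"], 1 / 3)
  expect_equal(M2["C02", "T2"], 2 / 3)
  expect_equal(unname(colSums(M2)), c(1, 1))   # partition identity
  empty <- structure(list(target_id = "T9", ligand_ids = character()),
                     class = "top_hit_set")
  expect_error(build_matrix2(c(fx$hits, list(empty)), fx$cl),
               class = "validation_error")
})

test_that("compound-target products match hand values and the loop oracle", {
  M <- rbind(C01 = c(T1 = 0.4, T2 = 0.1), C02 = c(0.8, 0.2))
  M <- structure(M, kind = "matrix1",
                 class = c("cluster_target_matrix", "matrix", "array"))
  # indicator row picks out M's row
  S <- rbind(x = c(C01 = 1, C02 = 0), y = c(0, 0), z = c(0.5, 0.5))
  P <- compound_target_scores(S, M)
  expect_equal(unname(P["x", ]), c(0.4, 0.1))
  expect_equal(unname(P["y", ]), c(0, 0))
  expect_equal(P["z", "T1"], 0.6)  # 0.5*0.4 + 0.5*0.8
  # naive triple loop on random matrices
  set.seed(14)
  for (rep in 1:10) {
    S2 <- matrix(runif(12), 3, 4,
                 dimnames = list(letters[1:3], sprintf("C%02d", 1:4)))
    M2 <- matrix(runif(8), 4, 2,
                 dimnames = list(sprintf("C%02d", 1:4), c("T1", "T2")))
    P2 <- compound_target_scores(S2, M2)
    for (i in 1:3) for (j in 1:2)
      expect_equal(P2[i, j], sum(S2[i, ] * M2[, j]), tolerance = 1e-12)
  }
  # misaligned cluster ids
  Mbad <- M; rownames(Mbad) <- c("C01", "C09")
  expect_error(compound_target_scores(S, Mbad), class = "alignment_error")
})

test_that("rank correlation reports r2 and the exact F identity", {
  x <- c(0.1, 0.4, 0.5, 0.9, 1.3, 2.0)
  y <- 10 - 4 * x
  v <- rank_correlation_validation(x, y)
  expect_equal(v$r2, 1.0)
  expect_equal(v$slope_sign, -1)
  # 12 hand pairs: F from r2 equals the ANOVA-table computation
  set.seed(6)
  x2 <- runif(12); y2 <- 3 * x2 + rnorm(12, sd = 0.5)
  v2 <- rank_correlation_validation(x2, y2)
  fit <- lm(y2 ~ x2)
  expect_equal(v2$F, summary(fit)$fstatistic[["value"]], tolerance = 1e-10)
  expect_equal(v2$r2, summary(fit)$r.squared, tolerance = 1e-12)
  expect_equal(v2$F, (v2$n - 2) * v2$r2 / (1 - v2$r2))
  expect_error(rank_correlation_validation(rep(1, 5), 1:5),
               class = "degenerate_regression")
})

test_that("independent score/rank pairs give near-zero r2", {
  set.seed(8)
  r2s <- replicate(100, {
    rank_correlation_validation(rnorm(1000), rnorm(1000))$r2
  })
  expect_lt(abs(mean(r2s) - 1 / 999), 5e-4)
})

test_that("binned ANOVA separates distant bins and flags degeneracy", {
  set.seed(10)
  scores <- c(runif(30, 0.0, 0.1), runif(30, 0.5, 0.6))
  ranks <- c(rnorm(30, 10), rnorm(30, 50))
  res <- binned_anova_tukey(scores, ranks, bin_width = 0.1)
  tb <- res$table
  expect_equal(nrow(tb), 2L)
  # well-separated means get disjoint letters
  expect_false(grepl(tb$letters[1], tb$letters[2], fixed = TRUE))
  expect_gt(res$F, 100)
  # all-identical observations: single letter, F undefined
  expect_warning(
    res2 <- binned_anova_tukey(c(0.05, 0.05, 0.55, 0.55), rep(3, 4)),
    class = "degenerate_anova_warning")
  expect_true(all(res2$table$letters == "a"))
  expect_true(is.na(res2$F))
  # sparse bins are dropped, and too few bins error
  expect_warning(
    expect_error(binned_anova_tukey(c(0.05, 0.15), c(1, 2)),
                 class = "insufficient_bins"),
    class = "sparse_bin_warning")
})

test_that("Tukey letters agree with pairwise Welch tests when separated", {
  set.seed(20)
  scores <- c(runif(25, 0, 0.1), runif(25, 0.2, 0.3), runif(25, 0.4, 0.5))
  ranks <- c(rnorm(25, 5, 1), rnorm(25, 30, 1), rnorm(25, 60, 1))
  res <- binned_anova_tukey(scores, ranks, bin_width = 0.1)
  expect_equal(length(unique(res$table$letters)), 3L)
  grp <- rep(1:3, each = 25)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_lt(t.test(ranks[grp == pair[1]], ranks[grp == pair[2]])$p.value,
              0.05)
})

test_that("equal-distribution bins share a letter at the nominal rate", {
  set.seed(30)
  share <- replicate(100, {
    scores <- runif(150, 0, 0.3)  # three 0.1 bins, same rank distribution
    ranks <- rnorm(150, 20, 5)
    res <- binned_anova_tukey(scores, ranks, bin_width = 0.1)
    lt <- res$table$letters
    any(vapply(strsplit(lt[1], "")[[1]], function(ch)
      all(grepl(ch, lt, fixed = TRUE)), logical(1)))
  })
  expect_gte(mean(share), 0.9)
})

test_that("likelihood binarization uses the strict 3.01 boundary", {
  S <- matrix(c(3.2, 2.5, 3.01, 0), 2, 2,
              dimnames = list(c("a", "b"), c("T1", "T2")))
  L <- build_likelihood(S)
  expect_equal(L["a", "T1"], 1)  # higher than 3.01 -> signature
  expect_equal(L["b", "T1"], 0)  # 2.5 -> no signature
  expect_equal(L["a", "T2"], 0)  # exactly 3.01 -> strict inequality
  expect_equal(attr(L, "threshold"), 3.01)
  # configurable cut
  expect_equal(unname(build_likelihood(S, 2)[, "T1"]), c(1, 1))
  S[1, 1] <- Inf
  expect_error(build_likelihood(S), class = "validation_error")
})
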