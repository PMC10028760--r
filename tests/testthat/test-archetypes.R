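# brute-force connected components at a distance threshold
components_oracle <- function(d, thr) {
  n <- nrow(d)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (d[i, j] <= thr && lab[j] != lab[i]) {
        lab[lab == lab[j]] <- lab[i]; changed <- TRUE
      }
    if (!changed) break
  }
  match(lab, unique(lab))
}

test_that("tree cutting recovers planted blocks and obeys edge cases", {
  d <- block_distmat(c(5, 7), within = 0.15, between = 0.85)
  cl <- hierarchical_cluster(d, "average", cutoff = 0.5)
  expect_equal(cl$n_clusters, 2L)
  oracle <- components_oracle(d, 0.5)
  # same partition as single-linkage components at this separation
  expect_equal(unname(table(cl$labels, oracle) > 0) * 1, diag(2))
  # first-appearance labelling
  expect_equal(unname(cl$labels[1]), "C01")
  # cutoff above max distance: one cluster
  expect_equal(hierarchical_cluster(d, "average", 1.01)$n_clusters, 1L)
  # cutoff 0 with all-distinct ligands: all singletons
  expect_equal(hierarchical_cluster(d, "average", 0)$n_clusters, nrow(d))
  bad <- d; bad[1, 2] <- 5
  expect_error(hierarchical_cluster(bad, "average", 0.5),
               class = "validation_error")
})

test_that("silhouette grid search finds a cutoff between the block scales", {
  d <- block_distmat(c(6, 6), within = 0.1, between = 0.85, jitter = 0.02)
  cc <- choose_cutoff(d, "average")
  # ties go to the smaller cutoff, so the choice sits just above the
  # within-block merge scale and well below the between-block scale
  expect_gt(cc$cutoff, 0.1)
  expect_lt(cc$cutoff, 0.8)
  expect_equal(hierarchical_cluster(d, "average", cc$cutoff)$n_clusters, 2L)
  # three equidistant blocks
  d3 <- block_distmat(c(5, 5, 5), within = 0.1, between = 0.8, seed = 3)
  cc3 <- choose_cutoff(d3, "average")
  expect_equal(hierarchical_cluster(d3, "average", cc3$cutoff)$n_clusters, 3L)
  # one tight block: every partition trivial
  d1 <- block_distmat(c(8), within = 0.05, jitter = 0.02, seed = 5)
  expect_error(choose_cutoff(d1, "average", grid = seq(0.2, 0.9, 0.1)),
               class = "no_structure")
})

test_that("centroids are member means in descriptor space", {
  d <- block_distmat(c(2, 1), within = 0.1, between = 0.9)
  cl <- hierarchical_cluster(d, "average", 0.5)
  Z <- rbind(L01 = c(1, 2), L02 = c(3, 4), L03 = c(10, 10))
  colnames(Z) <- c("d1", "d2")
  cen <- compute_centroids(cl, Z)
  expect_equal(cen["C01", ], c(d1 = 2, d2 = 3))
  expect_equal(cen["C02", ], c(d1 = 10, d2 = 10))  # singleton = its member
  # symmetric pair centred on the origin
  d2 <- block_distmat(c(2), within = 0.1)
  cl2 <- hierarchical_cluster(d2, "average", 0.5)
  Z2 <- rbind(L01 = c(2, -1), L02 = c(-2, 1))
  expect_equal(unname(compute_centroids(cl2, Z2)[1, ]), c(0, 0))
  expect_error(compute_centroids(cl, Z[1:2, ]), class = "missing_descriptor")
})

test_that("allocation is nearest-centroid with lowest-id ties", {
  cen <- rbind(C01 = c(0, 0), C02 = c(4, 0))
  at_centroid <- matrix(c(4, 0), 1, dimnames = list("x", NULL))
  a <- allocate_compounds(at_centroid, cen)
  expect_equal(a$cluster_id, "C02")
  expect_equal(a$distance, 0)
  halfway <- matrix(c(2, 0), 1, dimnames = list("x", NULL))
  expect_equal(allocate_compounds(halfway, cen)$cluster_id, "C01")
  expect_error(allocate_compounds(matrix(0, 1, 3,
                                         dimnames = list("x", NULL)), cen),
               class = "validation_error")
})

test_that("planted-family compounds allocate to their family", {
  set.seed(12)
  cen <- diag(3) * 3
  rownames(cen) <- sprintf("C%02d", 1:3)
  fam <- sample.int(3, 1000, replace = TRUE)
  pts <- cen[fam, ] + matrix(rnorm(3000, sd = 0.3), 1000, 3)
  rownames(pts) <- sprintf("p%04d", 1:1000)
  a <- allocate_compounds(pts, cen)
  expect_gte(mean(a$cluster_id == sprintf("C%02d", fam)), 0.95)
})

test_that("partitions are stable under input permutation", {
  d <- block_distmat(c(4, 5, 3), within = 0.2, between = 0.8, seed = 8)
  cl1 <- hierarchical_cluster(d, "average", 0.5)
  set.seed(8)
  perm <- sample(nrow(d))
  cl2 <- hierarchical_cluster(d[perm, perm], "average", 0.5)
  part <- function(cl) {
    unname(lapply(split(names(cl$labels), cl$labels), sort))
  }
  expect_setequal(part(cl1), part(cl2))
})

test_that("hierarchical clustering recovers planted scaffold families", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:10, function(s) {
    cfg <- synth_config(seed = s, n_families = 5, family_size = 8,
                        within_family_similarity = 0.6,
                        between_family_similarity = 0.2)
    fam <- gen_family_library(cfg)
    dm <- tanimoto_distance_matrix(fam$lib)
    cut <- choose_cutoff(dm, "average")$cutoff
    cl <- hierarchical_cluster(dm, "average", cut)
    mclust::adjustedRandIndex(cl$labels[names(fam$families)], fam$families)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("cluster members allocate back to their own centroid", {
  cfg <- synth_config(seed = 21)
  fam <- gen_family_library(cfg)
  dm <- tanimoto_distance_matrix(fam$lib)
  cl <- hierarchical_cluster(dm, "average", choose_cutoff(dm)$cutoff)
  Z <- zscore_descriptors(fam$descriptors)$zscored
  cen <- compute_centroids(cl, Z)
  a <- allocate_compounds(Z, cen)
  expect_equal(setNames(a$cluster_id, a$compound_id),
               cl$labels[a$compound_id])
  # idempotent: allocating twice gives the same assignment
  expect_identical(a, allocate_compounds(Z, cen))
})

test_that("dendrograms export as Newick text", {
  d <- block_distmat(c(3, 3), within = 0.1, between = 0.9)
  cl <- hierarchical_cluster(d, "average", 0.5)
  txt <- as_newick(cl)
  expect_match(txt, "^\\(.*\\);$")
  expect_true(all(vapply(rownames(d), grepl, logical(1), x = txt,
                         fixed = TRUE)))
})
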