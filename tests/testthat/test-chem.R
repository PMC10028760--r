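test_that("tanimoto similarity matches hand counts and conventions", {
  expect_equal(tanimoto_similarity(fp(c(1, 0, 1)), fp(c(1, 0, 1))), 1.0)
  expect_equal(tanimoto_similarity(fp(c(1, 1, 0)), fp(c(0, 0, 1))), 0.0)
  expect_equal(tanimoto_similarity(fp(c(1, 1, 0)), fp(c(0, 1, 1))), 1 / 3)
  # empty-vs-empty convention: identical absence
  expect_warning(s <- tanimoto_similarity(fp(c(0, 0)), fp(c(0, 0))),
                 class = "empty_fingerprint_warning")
  expect_equal(s, 1.0)
  expect_error(tanimoto_similarity(fp(c(1, 0)), fp(c(1, 0, 1))),
               class = "incompatible_fingerprint")
  expect_error(tanimoto_similarity(fp(c(1, 0), "a"), fp(c(1, 0), "b")),
               class = "incompatible_fingerprint")
})

test_that("tanimoto similarity is symmetric and equals the popcount oracle", {
  set.seed(42)
  fps <- random_fingerprints(60, n_bits = 64)
  for (trial in seq_len(1000)) {
    ij <- sample.int(60, 2)
    a <- fps[[ij[1]]]; b <- fps[[ij[2]]]
    s <- tanimoto_similarity(a, b)
    expect_identical(s, tanimoto_similarity(b, a))
    expect_equal(s, tanimoto_oracle(a, b), tolerance = 1e-15)
  }
})

test_that("tanimoto distance matrix is 1 - similarity with zero diagonal", {
  lib1 <- fixture_library(list(c(1, 1, 0)))
  expect_equal(unname(tanimoto_distance_matrix(lib1)), matrix(0, 1, 1))
  lib2 <- fixture_library(list(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(tanimoto_distance_matrix(lib2)["L01", "L02"], 0.0)
  lib3 <- fixture_library(list(c(1, 1, 0), c(0, 1, 1)))
  d <- tanimoto_distance_matrix(lib3)
  expect_equal(d["L01", "L02"], 2 / 3)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(L01 = 0, L02 = 0))
  empty <- ligand_library(character(0), character(0))
  expect_error(tanimoto_distance_matrix(empty), class = "empty_input")
})

test_that("deduplicate discards similarity-1 ligands, keeping first in order", {
  lib <- fixture_library(list(c(1, 0, 1), c(1, 0, 1)))
  res <- deduplicate(lib)
  expect_equal(res$kept$ligands$id, "L01")
  expect_equal(res$dropped,
               data.frame(kept_id = "L01", dropped_id = "L02",
                          stringsAsFactors = FALSE))
  distinct <- fixture_library(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(nrow(deduplicate(distinct)$dropped), 0L)
  # three mutually identical: transitive closure, 2 dropped pairs
  tri <- fixture_library(list(c(1, 1), c(1, 1), c(1, 1)))
  res3 <- deduplicate(tri)
  expect_equal(res3$kept$ligands$id, "L01")
  expect_equal(res3$dropped$dropped_id, c("L02", "L03"))
  expect_equal(res3$dropped$kept_id, c("L01", "L01"))
})

test_that("deduplicate is idempotent", {
  set.seed(7)
  rows <- c(random_fingerprints(20, n_bits = 16, p = 0.3),
            random_fingerprints(5, n_bits = 16, p = 0.3))
  lib <- ligand_library(sprintf("L%02d", 1:25), sprintf("L%02d", 1:25),
                        fingerprints = setNames(rows, sprintf("L%02d", 1:25)))
  once <- deduplicate(lib)
  twice <- deduplicate(once$kept)
  expect_equal(nrow(twice$dropped), 0L)
  expect_equal(twice$kept$ligands$id, once$kept$ligands$id)
})

test_that("collapse_enantiomers groups by flat key", {
  lib <- fixture_library(list(c(1, 0), c(1, 0), c(0, 1)),
                         ids = c("A_R", "A_S", "B"),
                         flat_keys = c("A", "A", "B"))
  res <- collapse_enantiomers(c("A_R", "A_S"), lib)
  expect_equal(res$unique_count, 1L)
  res2 <- collapse_enantiomers(c("A_R", "A_S", "B"), lib)
  expect_equal(res2$unique_count, 2L)
  expect_equal(res2$representatives, c("A_R", "B"))
  distinct <- fixture_library(list(c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(collapse_enantiomers(c("L01", "L02", "L03"), distinct)$unique_count,
               3L)
  expect_error(collapse_enantiomers("nope", lib), class = "missing_ligand")
  # never larger than the input id count
  set.seed(1)
  for (i in 1:20) {
    keys <- sample(letters[1:3], 5, replace = TRUE)
    l <- fixture_library(replicate(5, rbinom(8, 1, 0.5), simplify = FALSE),
                         flat_keys = keys)
    n <- sample.int(5, 1)
    ids <- sample(l$ligands$id, n)
    expect_lte(collapse_enantiomers(ids, l)$unique_count, n)
  }
})

test_that("SMILES and fingerprint sidecar files round-trip", {
  smi <- tempfile(fileext = ".txt")
  writeLines(c("# id SMILES", "lig1 CCO", "lig2\tCC(C)O", "", "lig3,CCCC"), smi)
  lib <- read_smiles(smi)
  expect_equal(lib$ligands$id, c("lig1", "lig2", "lig3"))
  expect_equal(lib$ligands$smiles, c("CCO", "CC(C)O", "CCCC"))
  set.seed(3)
  fps <- setNames(random_fingerprints(3, n_bits = 20), lib$ligands$id)
  sidecar <- tempfile(fileext = ".txt")
  write_fingerprints(fps, sidecar)
  back <- read_fingerprints(sidecar)
  for (id in names(fps))
    expect_identical(back[[id]]$bits, fps[[id]]$bits)
})

test_that("openbabel backend gives enantiomers one flat key", {
  skip_if_not_installed("ChemmineOB")
  lib <- ligand_library(c("R", "S"), c("C[C@H](N)O", "C[C@@H](N)O"),
                        backend = "openbabel")
  expect_false(lib$ligands$canonical_key[1] == lib$ligands$canonical_key[2])
  expect_equal(lib$ligands$flat_key[1], lib$ligands$flat_key[2])
})
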