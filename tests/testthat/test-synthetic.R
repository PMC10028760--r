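test_that("every generator is a pure function of (config, seed)", {
  cfg <- synth_config(seed = 77, n_targets = 2, n_functions = 2,
                      n_actives = 10, n_decoys = 40, n_ligands = 30,
                      n_models = 1, n_poses = 1)
  expect_identical(gen_benchmark(cfg), gen_benchmark(cfg))
  expect_identical(gen_family_library(cfg), gen_family_library(cfg))
  expect_identical(gen_planted_scores(cfg), gen_planted_scores(cfg))
  expect_identical(gen_chromatograms(cfg, letters),
                   gen_chromatograms(cfg, letters))
  expect_identical(gen_frame_stack(cfg), gen_frame_stack(cfg))
  cfg2 <- synth_config(seed = 78, n_targets = 2, n_functions = 2,
                       n_actives = 10, n_decoys = 40, n_ligands = 30,
                       n_models = 1, n_poses = 1)
  expect_false(identical(gen_benchmark(cfg)$table$score,
                         gen_benchmark(cfg2)$table$score))
})

test_that("benchmark AUC converges to the closed form Phi(shift / sqrt 2)", {
  cfg <- synth_config(seed = 5, n_targets = 1, n_functions = 1,
                      n_models = 1, n_poses = 1,
                      n_actives = 2000, n_decoys = 2000, active_shift = 2.5)
  b <- gen_benchmark(cfg)
  sc <- setNames(b$table$score, b$table$ligand_id)
  auc <- roc_auc(sc, b$benchmarks$T01, "lower_is_better")$auc
  expect_lt(abs(auc - pnorm(2.5 / sqrt(2))), 0.02)
})

test_that("zero-shift benchmarks are null-calibrated", {
  aucs <- vapply(1:100, function(s) {
    cfg <- synth_config(seed = s, n_targets = 1, n_functions = 1,
                        n_models = 1, n_poses = 1,
                        n_actives = 50, n_decoys = 150, active_shift = 0)
    b <- gen_benchmark(cfg)
    sc <- setNames(b$table$score, b$table$ligand_id)
    roc_auc(sc, b$benchmarks$T01, "lower_is_better")$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("family libraries hit their similarity targets on average", {
  cfg <- synth_config(seed = 13)
  fam <- gen_family_library(cfg)
  B <- eoscreen:::fingerprint_bit_matrix(fam$lib$fingerprints)
  sim <- eoscreen:::tanimoto_similarity_matrix(B)
  same <- outer(fam$families, fam$families, `==`)
  diag(same) <- NA
  within <- mean(sim[same & upper.tri(sim)], na.rm = TRUE)
  between <- mean(sim[!same & upper.tri(sim)], na.rm = TRUE)
  expect_lt(abs(within - cfg$within_family_similarity), 0.05)
  expect_lt(abs(between - cfg$between_family_similarity), 0.05)
  # infeasible similarity targets are rejected
  expect_error(gen_family_library(
    synth_config(within_family_similarity = 0.3,
                 between_family_similarity = 0.2)),
    class = "config_error")
  expect_error(gen_family_library(
    synth_config(within_family_similarity = 0.2,
                 between_family_similarity = 0.6)),
    class = "config_error")
})

test_that("chromatogram fractions are a seeded unit simplex", {
  cfg <- synth_config(seed = 3, n_species = 4, chromatogram_subset = 6)
  ch <- gen_chromatograms(cfg, sprintf("c%02d", 1:20))
  sums <- tapply(ch$fraction, ch$species, sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-9)
  cfg1 <- synth_config(seed = 3, n_species = 2, chromatogram_subset = 1)
  ch1 <- gen_chromatograms(cfg1, sprintf("c%02d", 1:20))
  expect_equal(ch1$fraction, c(1, 1))
})

test_that("blob stacks obey the disjoint-support geometry", {
  frames <- function(jump) list(n = 10, height = 40, width = 80,
                                blob_diameter = 9, jump_px = jump)
  m0 <- average_motility(gen_frame_stack(synth_config(frames = frames(0))))
  expect_equal(m0, 0)
  # jump >= diameter: consecutive masks disjoint
  m9 <- average_motility(gen_frame_stack(synth_config(frames = frames(9))))
  expect_equal(m9, 1)
  # blob too large for the frame
  expect_error(gen_frame_stack(synth_config(
    frames = list(n = 5, height = 10, width = 10, blob_diameter = 9,
                  jump_px = 2))), class = "config_error")
})

test_that("demo datasets round-trip through the file readers", {
  cfg <- synth_config(seed = 11, n_targets = 2, n_functions = 2,
                      n_models = 1, n_poses = 1, n_ligands = 90,
                      n_actives = 10, n_decoys = 40,
                      n_families = 3, family_size = 4, n_species = 2,
                      chromatogram_subset = 4,
                      frames = list(n = 4, height = 24, width = 48,
                                    blob_diameter = 7, jump_px = 2))
  dir <- file.path(tempdir(), "demo_ds")
  write_demo_dataset(cfg, dir)
  ors <- read_orientations(file.path(dir, "orientations.cfg"))
  tab <- read_score_table(file.path(dir, "scores.csv"), ors)
  study <- gen_study(cfg)
  expect_equal(nrow(tab), nrow(study$scores$table))
  expect_equal(sort(unique(tab$function_id)), c("FN1", "FN2"))
  lib <- read_smiles(file.path(dir, "smiles.txt"))
  expect_setequal(lib$ligands$id, study$lib$ligands$id)
  fps <- read_fingerprints(file.path(dir, "fingerprints.txt"))
  expect_identical(fps[["HIT_F01_M01"]]$bits,
                   study$lib$fingerprints[["HIT_F01_M01"]]$bits)
  desc <- read_descriptors(file.path(dir, "descriptors.csv"))
  expect_equal(desc, study$descriptors, tolerance = 1e-6)
  ch <- read_chromatogram(file.path(dir, "chromatograms.csv"))
  expect_equal(nrow(ch), nrow(study$chromatograms))
  expect_length(read_frame_stack(file.path(dir, "frames")), 4L)
})
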