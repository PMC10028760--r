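#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives every generator, so a full pipeline run
#' is a pure function of this object. Defaults mirror the screening study
#' the package emulates: 8 insect protein targets, 5 scoring functions
#' (Vina-like energies, lower is better), 3 homology models per target, a
#' 651-compound natural-product library, and a 50-active / 950-decoy
#' validation benchmark whose active scores are shifted by 2.5 sd (giving a
#' theoretical AUC of `pnorm(2.5 / sqrt(2))`, about 0.96).
#'
#' @param seed integer seed.
#' @param n_targets,n_functions,n_models,n_poses docking design dimensions.
#' @param n_ligands library size for planted-hit score tables.
#' @param n_planted,planted_shift number of planted top ligands per target
#'   and their goodness shift in sd units.
#' @param mu0 decoy score mean (kcal/mol-like, lower is better).
#' @param n_actives,n_decoys,active_shift benchmark composition and the
#'   actives' shift in sd units.
#' @param n_families,family_size planted scaffold families.
#' @param within_family_similarity,between_family_similarity expected
#'   Tanimoto targets inside and between families.
#' @param n_bits fingerprint length for generated bitsets.
#' @param n_descriptors,descriptor_sd,centroid_separation descriptor-space
#'   family geometry: member scatter sd and minimum centroid separation.
#' @param n_species,chromatogram_subset chromatogram generation: species
#'   count and compounds per species.
#' @param frames list (n, height, width, blob_diameter, jump_px) for the
#'   larva-blob frame stacks.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_targets = 8L, n_functions = 5L,
                         n_models = 3L, n_poses = 3L, n_ligands = 651L,
                         n_planted = 10L, planted_shift = 3,
                         mu0 = -6.5, n_actives = 50L, n_decoys = 950L,
                         active_shift = 2.5,
                         n_families = 5L, family_size = 8L,
                         within_family_similarity = 0.6,
                         between_family_similarity = 0.2,
                         n_bits = 1024L, n_descriptors = 8L,
                         descriptor_sd = 0.3, centroid_separation = 3,
                         n_species = 5L, chromatogram_subset = 10L,
                         frames = list(n = 30L, height = 64L, width = 64L,
                                       blob_diameter = 9L, jump_px = 2L)) {
  cfg <- as.list(environment())
  counts <- c("n_targets", "n_functions", "n_models", "n_poses", "n_ligands",
              "n_families", "family_size", "n_bits", "n_descriptors",
              "n_species")
  for (nm in counts)
    if (cfg[[nm]] < 1L) eo_stop(sprintf("%s must be positive", nm),
                                "config_error")
  if (active_shift < 0) eo_stop("active_shift must be >= 0", "config_error")
  structure(cfg, class = "synth_config")
}

synth_targets <- function(cfg) sprintf("T%02d", seq_len(cfg$n_targets))
synth_functions <- function(cfg) sprintf("FN%d", seq_len(cfg$n_functions))
synth_orientations <- function(cfg)
  stats::setNames(rep("lower_is_better", cfg$n_functions),
                  synth_functions(cfg))

#' Generate an actives/decoys scoring benchmark
#'
#' Decoy scores are Normal(mu0, 1) and active scores Normal(mu0 -
#' active_shift, 1), independently per (target, function, model, pose),
#' lower is better. With a single model and pose, the per-function AUC
#' converges to `pnorm(active_shift / sqrt(2))`.
#'
#' @param cfg a [synth_config()].
#' @param n_models,n_poses overrides of the docking design for the
#'   benchmark (defaults: the config values).
#' @return list with `table` (a [score_table()]) and `benchmarks` (named
#'   list of [benchmark_set()] per target).
#' @export
gen_benchmark <- function(cfg, n_models = cfg$n_models,
                          n_poses = cfg$n_poses) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    targets <- synth_targets(cfg)
    funs <- synth_functions(cfg)
    ids <- c(sprintf("ACT%04d", seq_len(cfg$n_actives)),
             sprintf("DEC%04d", seq_len(cfg$n_decoys)))
    is_active <- c(rep(TRUE, cfg$n_actives), rep(FALSE, cfg$n_decoys))
    grid <- expand.grid(ligand_id = ids, target_id = targets,
                        model_id = sprintf("M%d", seq_len(n_models)),
                        function_id = funs,
                        pose_rank = seq_len(n_poses),
                        stringsAsFactors = FALSE)
    mu <- cfg$mu0 - cfg$active_shift * is_active[match(grid$ligand_id, ids)]
    grid$score <- stats::rnorm(nrow(grid), mean = mu, sd = 1)
    benchmarks <- lapply(stats::setNames(targets, targets), function(t)
      benchmark_set(t, stats::setNames(ifelse(is_active, "active", "decoy"),
                                       ids)))
    list(table = score_table(grid, synth_orientations(cfg)),
         benchmarks = benchmarks)
  })
}

# expected Tanimoto between two members that each flip a fraction q of the
# n bits of a base fingerprint with ones-density d
expected_within_tanimoto <- function(q, d) {
  num <- d * (1 - q)^2 + (1 - d) * q^2
  den <- d * (1 - q^2) + (1 - d) * q * (2 - q)
  num / den
}

#' Generate a ligand library with planted scaffold families
#'
#' Each family gets a random base fingerprint; members flip a fixed number
#' of bits, calibrated analytically so the expected within-family Tanimoto
#' hits `within_family_similarity` while unrelated bases sit near
#' `between_family_similarity` (the ones-density is chosen as
#' `2 b / (1 + b)`). Descriptor vectors scatter around orthogonal family
#' centroids separated by `centroid_separation` with sd `descriptor_sd`.
#'
#' @param cfg a [synth_config()].
#' @param id_prefix prefix for generated ligand ids.
#' @param seed_offset added to `cfg$seed` so several libraries (e.g. hits
#'   and essential-oil compounds) can be drawn from one config.
#' @return list with `lib` (a [ligand_library()] with fingerprints),
#'   `descriptors` (raw matrix), and `families` (named family labels).
#' @export
gen_family_library <- function(cfg, id_prefix = "L", seed_offset = 0L) {
  stopifnot(inherits(cfg, "synth_config"))
  b <- cfg$between_family_similarity
  w <- cfg$within_family_similarity
  if (w <= b) eo_stop("within-family similarity must exceed between-family",
                      "config_error")
  d <- 2 * b / (1 + b)
  lo <- expected_within_tanimoto(0.5, d)
  if (w <= lo + 1e-9)
    eo_stop(sprintf(
      "within-family similarity %.2f infeasible for n_bits flips (floor %.2f)",
      w, lo), "config_error")
  q <- stats::uniroot(function(q) expected_within_tanimoto(q, d) - w,
                      c(1e-9, 0.5))$root
  n_flip <- max(1L, round(q * cfg$n_bits))
  if (cfg$n_families > cfg$n_descriptors)
    eo_stop("need n_descriptors >= n_families for separated centroids",
            "config_error")
  # family bases depend on cfg$seed only, so libraries drawn with different
  # seed_offset (hits vs essential-oil compounds) share scaffold identity
  bases <- with_seed(cfg$seed + 211L,
                     lapply(seq_len(cfg$n_families), function(f)
                       stats::runif(cfg$n_bits) < d))
  with_seed(cfg$seed + seed_offset, {
    centroids <- diag(cfg$n_families) * cfg$centroid_separation / sqrt(2)
    centroids <- cbind(centroids,
                       matrix(0, cfg$n_families,
                              cfg$n_descriptors - cfg$n_families))
    ids <- character(); fams <- character()
    fps <- list(); desc <- NULL
    for (f in seq_len(cfg$n_families)) {
      base <- bases[[f]]
      for (m in seq_len(cfg$family_size)) {
        id <- sprintf("%s_F%02d_M%02d", id_prefix, f, m)
        flip <- sample.int(cfg$n_bits, n_flip)
        bits <- base
        bits[flip] <- !bits[flip]
        fps[[id]] <- fingerprint(bits, scheme_id = "synthetic")
        ids <- c(ids, id); fams <- c(fams, sprintf("F%02d", f))
        desc <- rbind(desc, stats::rnorm(cfg$n_descriptors,
                                         mean = centroids[f, ],
                                         sd = cfg$descriptor_sd))
      }
    }
    rownames(desc) <- ids
    colnames(desc) <- sprintf("D%02d", seq_len(cfg$n_descriptors))
    lib <- ligand_library(ids, smiles = paste0("SYN:", ids),
                          fingerprints = fps)
    list(lib = lib, descriptors = desc,
         families = stats::setNames(fams, ids))
  })
}

#' Generate a docking score table with planted top ligands
#'
#' Scores are Normal(mu0, 1) per (ligand, target, function, model, pose),
#' lower is better; each target's planted ligands get their mean shifted
#' down (better) by `planted_shift` sd across every function, emulating
#' compounds that every scoring function agrees are strong binders.
#'
#' @param cfg a [synth_config()].
#' @param ligand_ids ligands to score (default: `n_ligands` generated ids).
#' @param planted named list target_id -> planted ligand ids (default:
#'   `n_planted` ligands per target drawn without replacement).
#' @return list with `table` (a [score_table()]) and `planted`.
#' @export
gen_planted_scores <- function(cfg, ligand_ids = NULL, planted = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 1L, {
    if (is.null(ligand_ids))
      ligand_ids <- sprintf("LIG%04d", seq_len(cfg$n_ligands))
    targets <- synth_targets(cfg)
    if (is.null(planted))
      planted <- lapply(stats::setNames(targets, targets), function(t)
        sample(ligand_ids, cfg$n_planted))
    grid <- expand.grid(ligand_id = ligand_ids, target_id = targets,
                        model_id = sprintf("M%d", seq_len(cfg$n_models)),
                        function_id = synth_functions(cfg),
                        pose_rank = seq_len(cfg$n_poses),
                        stringsAsFactors = FALSE)
    shift <- numeric(nrow(grid))
    for (t in targets)
      shift[grid$target_id == t &
              grid$ligand_id %in% planted[[t]]] <- cfg$planted_shift
    grid$score <- stats::rnorm(nrow(grid), mean = cfg$mu0 - shift, sd = 1)
    list(table = score_table(grid, synth_orientations(cfg)),
         planted = planted)
  })
}

#' Generate chromatogram profiles over a compound registry
#'
#' Per species, a random subset of compounds receives Dirichlet(1)
#' (uniform-simplex) area fractions summing to one.
#'
#' @param cfg a [synth_config()].
#' @param compound_ids compound registry to draw from.
#' @return A [chromatogram_set()].
#' @export
gen_chromatograms <- function(cfg, compound_ids) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 2L, {
    rows <- lapply(seq_len(cfg$n_species), function(s) {
      m <- min(cfg$chromatogram_subset, length(compound_ids))
      picked <- sample(compound_ids, m)
      g <- stats::rgamma(m, shape = 1)
      data.frame(species = sprintf("SP%02d", s), compound_id = picked,
                 fraction = g / sum(g), stringsAsFactors = FALSE)
    })
    chromatogram_set(do.call(rbind, rows))
  })
}

#' Generate a frame stack with a moving larva-like blob
#'
#' A disc of the configured diameter moves `jump_px` pixels per frame along
#' a fixed horizontal path, bouncing inside a margin so the mask never
#' touches the frame border. `jump_px = 0` gives motility 0;
#' `jump_px >= blob_diameter` makes consecutive masks disjoint (motility
#' 1); in between, motility increases with the jump distance.
#'
#' @param cfg a [synth_config()]; geometry comes from `cfg$frames`.
#' @param grayscale emit grayscale frames (background `bg`, blob `fg`)
#'   instead of binary masks, e.g. to exercise Otsu binarization.
#' @param fg,bg grayscale levels used when `grayscale = TRUE`.
#' @return A [frame_stack()] (binary unless `grayscale`).
#' @export
gen_frame_stack <- function(cfg, grayscale = FALSE, fg = 0.9, bg = 0.1) {
  stopifnot(inherits(cfg, "synth_config"))
  fr <- cfg$frames
  r <- (fr$blob_diameter - 1) / 2
  margin <- ceiling(r) + 2
  lo <- margin; hi <- fr$width - margin
  if (hi - lo < max(1, fr$jump_px))
    eo_stop("blob path does not fit the frame: enlarge width or shrink blob/jump",
            "config_error")
  cy <- (fr$height + 1) / 2
  if (cy - r < 2 || cy + r > fr$height - 1)
    eo_stop("blob does not fit the frame height", "config_error")
  cx <- lo; dir <- 1
  frames <- vector("list", fr$n)
  for (i in seq_len(fr$n)) {
    m <- matrix(0, fr$height, fr$width)
    ys <- seq_len(fr$height); xs <- seq_len(fr$width)
    m[outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2] <- 1
    frames[[i]] <- if (grayscale) bg + (fg - bg) * m else m
    nxt <- cx + dir * fr$jump_px
    if (nxt > hi || nxt < lo) dir <- -dir
    cx <- cx + dir * fr$jump_px
  }
  frame_stack(frames, source_id = sprintf("synthetic_jump%d", fr$jump_px))
}

#' Write a complete synthetic demo dataset to a directory
#'
#' Emits scores.csv, labels.csv, smiles.txt, fingerprints.txt,
#' descriptors.csv, chromatograms.csv, orientations.cfg and a frames/
#' directory of PNGs, all generated from one seeded config — a
#' self-contained input set for the full pipeline.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_demo_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- gen_study(cfg)
  write_score_table(study$scores$table, file.path(dir, "scores.csv"))
  bench <- gen_benchmark(cfg, n_models = 1L, n_poses = 1L)
  write_score_table(bench$table, file.path(dir, "benchmark_scores.csv"))
  labs <- do.call(rbind, lapply(bench$benchmarks, function(b)
    data.frame(ligand_id = names(b$labels), target_id = b$target_id,
               label = unname(b$labels))))
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  lig <- study$lib$ligands
  writeLines(c("# id SMILES", paste(lig$id, lig$smiles)),
             file.path(dir, "smiles.txt"))
  write_fingerprints(study$lib$fingerprints, file.path(dir, "fingerprints.txt"))
  write_matrix_csv(study$descriptors, file.path(dir, "descriptors.csv"),
                   rowname_header = "compound_id")
  utils::write.csv(as.data.frame(study$chromatograms),
                   file.path(dir, "chromatograms.csv"), row.names = FALSE,
                   quote = FALSE)
  ors <- synth_orientations(cfg)
  writeLines(paste0(names(ors), "=", ors), file.path(dir, "orientations.cfg"))
  write_frame_stack(gen_frame_stack(cfg, grayscale = TRUE),
                    file.path(dir, "frames"))
  invisible(dir)
}

#' Generate a coherent end-to-end synthetic study
#'
#' Ties the generators together the way the real inputs relate: the library
#' holds the planted scaffold families plus unstructured filler compounds;
#' each target's planted top ligands are one family's members, so hit
#' selection, archetype clustering and the association matrices have
#' recoverable structure; essential-oil compounds are fresh draws from the
#' same families (chromatography source) and inherit their family's
#' affinity in the score table.
#'
#' @param cfg a [synth_config()].
#' @return list with `lib` (database + chromatography ligands),
#'   `descriptors` (raw matrix over all ligands), `families`,
#'   `eo_compound_ids`, `scores` (list: table, planted), `chromatograms`,
#'   and `target_family` (which family was planted for each target).
#' @export
gen_study <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  fam <- gen_family_library(cfg, id_prefix = "HIT")
  eo <- gen_family_library(cfg, id_prefix = "EO", seed_offset = 17L)
  n_fill <- max(0L, cfg$n_ligands - length(fam$lib) - length(eo$lib))
  d <- 2 * cfg$between_family_similarity / (1 + cfg$between_family_similarity)
  filler <- with_seed(cfg$seed + 3L, {
    ids <- if (n_fill) sprintf("LIG%04d", seq_len(n_fill)) else character()
    fps <- lapply(stats::setNames(ids, ids), function(i)
      fingerprint(stats::runif(cfg$n_bits) < d, scheme_id = "synthetic"))
    desc <- matrix(stats::rnorm(n_fill * cfg$n_descriptors, sd = 1.5),
                   nrow = n_fill,
                   dimnames = list(ids, colnames(fam$descriptors)))
    list(ids = ids, fps = fps, desc = desc)
  })
  ids <- c(fam$lib$ligands$id, filler$ids, eo$lib$ligands$id)
  lib <- ligand_library(
    ids, smiles = paste0("SYN:", ids),
    fingerprints = c(fam$lib$fingerprints, filler$fps, eo$lib$fingerprints),
    source = rep(c("database", "chromatography"),
                 c(length(fam$lib) + n_fill, length(eo$lib))))
  descriptors <- rbind(fam$descriptors, filler$desc, eo$descriptors)
  # plant one family per target (recycled when targets outnumber families)
  targets <- synth_targets(cfg)
  fam_of_target <- sprintf("F%02d",
                           rep_len(seq_len(cfg$n_families), cfg$n_targets))
  names(fam_of_target) <- targets
  planted <- lapply(fam_of_target, function(f) {
    members <- names(fam$families)[fam$families == f]
    eo_members <- names(eo$families)[eo$families == f]
    c(members, eo_members)
  })
  scores <- gen_planted_scores(cfg, ligand_ids = ids, planted = planted)
  chrom <- gen_chromatograms(cfg, eo$lib$ligands$id)
  list(lib = lib, descriptors = descriptors,
       families = c(fam$families, eo$families),
       eo_compound_ids = eo$lib$ligands$id,
       scores = scores, chromatograms = chrom,
       target_family = fam_of_target)
}
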