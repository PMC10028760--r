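#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with every
#' tunable at its documented default. Unknown keys passed by the user are
#' rejected, so typos never silently fall back to defaults.
#'
#' @return Named list of configuration defaults.
#' @export
default_pipeline_config <- function() {
  list(
    synthetic = TRUE,          # generate inputs from `synth`; else read `inputs`
    seed = 1L,
    synth = list(),            # overrides forwarded to synth_config()
    inputs = list(),           # file paths when synthetic = FALSE
    auc_min = 0.5,             # scoring-function selection rule
    efmax_fraction_max = 0.05,
    ef_fractions = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1),
    force_include = character(),
    selector = "kmeans",       # "kmeans" (successive) or "fraction" (top 1%)
    k = 3L,
    hit_range = c(8L, 12L),
    fraction = 0.01,
    max_iter = 50L,
    linkage = "average",
    cutoff = NULL,             # NULL = silhouette-chosen on cutoff_grid
    cutoff_grid = seq(0.05, 0.95, by = 0.05),
    ddof = 1,
    bdstfl_stat = "mean",
    bin_width = 0.1,
    alpha = 0.05,
    threshold = 3.01,
    weighting = "binary_likelihood")
}

merge_config <- function(config) {
  defaults <- default_pipeline_config()
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- config %||% list()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    eo_stop(sprintf("unknown configuration key(s): %s",
                    paste(unknown, collapse = ", ")), "config_error")
  out <- utils::modifyList(defaults, config)
  out$seed <- as.integer(out$seed)
  out
}

stage_writer <- function(out_dir, manifest_env) {
  function(stage, fun) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        manifest_env$manifest$failed_stage <- stage
        write_manifest(out_dir, manifest_env$manifest)
        eo_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                "stage_failure")
      }),
      warning = function(w) {
        manifest_env$manifest$warnings <-
          c(manifest_env$manifest$warnings,
            sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest_env$manifest$stages[[stage]] <-
      list(seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    res
  }
}

write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full screening post-processing pipeline
#'
#' Executes the stages in order — validate scoring functions, select
#' per-target hits, cluster archetypes, build similarity matrices, build
#' association matrices and the likelihood matrix, predict essential-oil
#' profiles — writing every stage's output as CSV/JSON into `out_dir`
#' together with a manifest recording the configuration hash, seed, stage
#' timings and collected warnings. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML/JSON file of overrides.
#' @param out_dir output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- merge_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null")
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  menv <- new.env()
  menv$manifest <- list(
    package_version = as.character(utils::packageVersion("eoscreen")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = list(), warnings = character())
  run <- stage_writer(out_dir, menv)

  data <- run("load_inputs", function() load_pipeline_inputs(cfg))

  validation <- run("validate_functions", function() {
    agg <- list(best = aggregate_scores(data$bench_table, "best"),
                top3_mean = aggregate_scores(data$bench_table, "top3_mean"))
    ors <- orientations_of(data$bench_table)
    sel <- list()
    for (t in names(data$benchmarks)) {
      results <- list()
      for (f in unique(data$bench_table$function_id))
        for (m in names(agg)) {
          a <- agg[[m]]
          sc <- a$score[a$target_id == t & a$function_id == f]
          names(sc) <- a$ligand_id[a$target_id == t & a$function_id == f]
          results[[paste(f, m)]] <- evaluate_function(
            sc, data$benchmarks[[t]], ors[[f]],
            fractions = cfg$ef_fractions, function_id = f, mode = m)
        }
      tab <- select_functions(results, cfg$auc_min, cfg$efmax_fraction_max,
                              cfg$force_include)
      tab <- cbind(target_id = t, tab)
      sel[[t]] <- tab
    }
    sel_tab <- do.call(rbind, sel)
    utils::write.csv(sel_tab, file.path(out_dir, "function_selection.csv"),
                     row.names = FALSE, quote = FALSE)
    sel_tab
  })

  hits <- run("select_hits", function() {
    agg <- list(best = aggregate_scores(data$score_table, "best"),
                top3_mean = aggregate_scores(data$score_table, "top3_mean"))
    out <- list()
    for (t in unique(data$score_table$target_id)) {
      sel <- validation[validation$target_id == t & validation$selected, ]
      if (!nrow(sel))
        sel <- validation[validation$target_id == t, ][
          which.max(validation$auc[validation$target_id == t]), ]
      if (cfg$selector == "fraction") {
        out[[t]] <- top_fraction_hits(agg[[sel$mode[1L]]], t, cfg$fraction,
                                      sel$function_id, data$lib)
      } else {
        G <- do.call(cbind, lapply(seq_len(nrow(sel)), function(i)
          goodness_matrix(agg[[sel$mode[i]]], t, sel$function_id[i])))
        vs <- structure(list(target_id = t, function_ids = sel$function_id,
                             vectors = standardize_columns(G)),
                        class = "score_vector_set")
        out[[t]] <- iterative_kmeans_select(vs, data$lib, k = cfg$k,
                                            range = cfg$hit_range,
                                            seed = cfg$seed,
                                            max_iter = cfg$max_iter)
      }
    }
    hits_tab <- do.call(rbind, lapply(out, function(h)
      data.frame(target_id = h$target_id, ligand_id = h$ligand_ids,
                 selection_method = cfg$selector, iterations = h$iterations,
                 seed = h$seed)))
    utils::write.csv(hits_tab, file.path(out_dir, "hits.csv"),
                     row.names = FALSE, quote = FALSE)
    out
  })

  clustering <- run("cluster", function() {
    pooled <- pool_hits(hits, data$lib)
    dm <- tanimoto_distance_matrix(subset_library(data$lib, pooled))
    cutoff <- cfg$cutoff %||% choose_cutoff(dm, cfg$linkage,
                                            cfg$cutoff_grid)$cutoff
    cl <- hierarchical_cluster(dm, cfg$linkage, cutoff)
    utils::write.csv(data.frame(ligand_id = names(cl$labels),
                                cluster_id = unname(cl$labels)),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE,
                     quote = FALSE)
    if (!is.null(cl$tree)) as_newick(cl, file.path(out_dir, "dendrogram.nwk"))
    cl
  })

  simmats <- run("similarity", function() {
    ids <- union(names(clustering$labels), data$eo_compound_ids)
    Z <- zscore_descriptors(data$descriptors[ids, , drop = FALSE],
                            ddof = cfg$ddof)$zscored
    centroids <- compute_centroids(clustering, Z)
    P <- epnmcs(Z[data$eo_compound_ids, , drop = FALSE], centroids)
    B <- bdstfl(data$lib, clustering, data$eo_compound_ids,
                stat = cfg$bdstfl_stat)
    write_matrix_csv(centroids, file.path(out_dir, "centroids.csv"),
                     "cluster_id")
    write_matrix_csv(unclass(P), file.path(out_dir, "epnmcs.csv"),
                     "compound_id")
    write_matrix_csv(unclass(B), file.path(out_dir, "bdstfl.csv"),
                     "compound_id")
    list(P = P, B = B, centroids = centroids)
  })

  assoc <- run("associate", function() {
    M1 <- build_matrix1(hits, clustering)
    M2 <- build_matrix2(hits, clustering)
    write_matrix_csv(unclass(M1), file.path(out_dir, "matrix1.csv"),
                     "cluster_id")
    write_matrix_csv(unclass(M2), file.path(out_dir, "matrix2.csv"),
                     "cluster_id")
    agg <- aggregate_scores(data$score_table, "best")
    rank_mat <- sapply(colnames(M1), function(t) {
      rk <- rank_ligands(agg, t)
      stats::setNames(rk$mean_rank, rk$ligand_id)[data$eo_compound_ids]
    })
    combos <- list(product_m1_epnmcs = compound_target_scores(simmats$P, M1),
                   product_m2_epnmcs = compound_target_scores(simmats$P, M2),
                   product_m1_bdstfl = compound_target_scores(simmats$B, M1),
                   product_m2_bdstfl = compound_target_scores(simmats$B, M2))
    validations <- lapply(combos, function(S)
      rank_correlation_validation(S, rank_mat))
    for (nm in names(combos))
      write_matrix_csv(unclass(combos[[nm]]),
                       file.path(out_dir, paste0(nm, ".csv")), "compound_id")
    jsonlite::write_json(validations,
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tukey <- tryCatch(
      binned_anova_tukey(combos$product_m1_epnmcs, rank_mat,
                         cfg$bin_width, cfg$alpha),
      eoscreen_error = function(e) NULL)
    if (!is.null(tukey))
      utils::write.csv(tukey$table, file.path(out_dir, "tukey_bins.csv"),
                       row.names = FALSE, quote = FALSE)
    L <- build_likelihood(combos$product_m1_epnmcs, cfg$threshold)
    write_matrix_csv(unclass(L), file.path(out_dir, "likelihood.csv"),
                     "compound_id")
    list(M1 = M1, M2 = M2, combos = combos, validations = validations,
         likelihood = L, rank_mat = rank_mat)
  })

  profiles <- run("predict", function() {
    W <- if (cfg$weighting == "binary_likelihood") assoc$likelihood
         else assoc$combos$product_m1_epnmcs
    prof <- predict_profile(data$chromatograms, W, cfg$weighting)
    write_profile(prof, file.path(out_dir, "profiles.csv"),
                  file.path(out_dir, "profiles_report.json"))
    cont <- predict_profile(data$chromatograms,
                            assoc$combos$product_m1_epnmcs,
                            "continuous_score")
    write_profile(cont, file.path(out_dir, "profiles_continuous.csv"))
    list(profile = prof, continuous = cont)
  })

  menv$manifest$n_stages <- length(menv$manifest$stages)
  write_manifest(out_dir, menv$manifest)
  invisible(list(manifest = menv$manifest, data = data, hits = hits,
                 clustering = clustering, simmats = simmats, assoc = assoc,
                 profiles = profiles, validation = validation))
}

load_pipeline_inputs <- function(cfg) {
  if (isTRUE(cfg$synthetic)) {
    scfg <- do.call(synth_config, utils::modifyList(list(seed = cfg$seed),
                                                    as.list(cfg$synth)))
    study <- gen_study(scfg)
    bench <- gen_benchmark(scfg, n_models = 1L, n_poses = 1L)
    list(lib = study$lib, descriptors = study$descriptors,
         score_table = study$scores$table, bench_table = bench$table,
         benchmarks = bench$benchmarks,
         eo_compound_ids = study$eo_compound_ids,
         chromatograms = study$chromatograms,
         planted = study$scores$planted, families = study$families)
  } else {
    ins <- cfg$inputs
    need <- c("scores", "benchmark_scores", "labels", "smiles",
              "fingerprints", "descriptors", "chromatograms", "orientations")
    miss <- setdiff(need, names(ins))
    if (length(miss))
      eo_stop(sprintf("missing input path(s): %s",
                      paste(miss, collapse = ", ")), "config_error")
    for (p in unlist(ins))
      if (!file.exists(p))
        eo_stop(sprintf("input file not found: %s", p), "data_error")
    ors <- read_orientations(ins$orientations)
    lib <- read_smiles(ins$smiles, backend = "identity")
    lib$fingerprints <- read_fingerprints(ins$fingerprints)
    chrom <- read_chromatogram(ins$chromatograms)
    list(lib = lib,
         descriptors = read_descriptors(ins$descriptors),
         score_table = read_score_table(ins$scores, ors),
         bench_table = read_score_table(ins$benchmark_scores, ors),
         benchmarks = read_benchmarks(ins$labels),
         eo_compound_ids = unique(chrom$compound_id),
         chromatograms = chrom)
  }
}
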