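#' Standardized score-vector sets
#'
#' For one target, each ligand gets an N-dimensional vector of the scores
#' given by the N selected functions, converted to goodness (larger =
#' better) and standardized per function to mean 0, sd 1 over the current
#' ligand set.
#'
#' @param agg an [aggregate_scores()] result.
#' @param target_id target of interest.
#' @param function_ids the selected scoring functions.
#' @return A `score_vector_set`: list with `target_id`, `function_ids`, and
#'   `vectors` (ligand x function matrix of standardized goodness).
#' @export
score_vector_set <- function(agg, target_id, function_ids) {
  G <- goodness_matrix(agg, target_id, function_ids)
  if (anyNA(G))
    eo_stop("incomplete score vectors: every ligand needs all selected functions",
            "validation_error")
  structure(list(target_id = target_id, function_ids = function_ids,
                 vectors = standardize_columns(G)),
            class = "score_vector_set")
}

standardize_columns <- function(M) {
  apply(M, 2L, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
}

#' Select per-target top hits by successive k-means
#'
#' Repeatedly k-means-clusters the ligands' standardized score vectors and
#' keeps the cluster with the best combination of scores, until the
#' surviving set contains between `range[1]` and `range[2]` unique ligands
#' not counting enantiomers. The surviving set is re-standardized before
#' each iteration so that later rounds discriminate among already-good
#' ligands. If a step would drop below `range[1]` unique ligands, the
#' previous set is kept and trimmed to `range[2]` unique ligands by mean
#' rank.
#'
#' @param vs a [score_vector_set()].
#' @param lib a [ligand_library()] supplying `flat_key`s for enantiomer
#'   collapsing.
#' @param k number of k-means clusters per iteration.
#' @param range target range (min, max) for the enantiomer-collapsed hit
#'   count.
#' @param seed integer seed; selection is bit-reproducible given (inputs,
#'   seed).
#' @param max_iter iteration cap; exceeding it raises a non-convergence
#'   error carrying the partial ligand set.
#' @param strategy how the "best" cluster is scored: highest centroid mean
#'   over dimensions (default) or highest worst dimension.
#' @return A `top_hit_set`: list with `target_id`, `ligand_ids`,
#'   `unique_count`, `iterations`, `seed`.
#' @export
iterative_kmeans_select <- function(vs, lib, k = 3L, range = c(8L, 12L),
                                    seed = 1L, max_iter = 50L,
                                    strategy = c("centroid_mean",
                                                 "worst_dimension")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(vs, "score_vector_set"))
  X <- vs$vectors
  if (k < 2L) eo_stop("k must be >= 2", "validation_error")
  ids <- rownames(X)
  iter <- 0L
  in_range <- function(ids) {
    u <- collapse_enantiomers(ids, lib)$unique_count
    list(u = u, ok = u >= range[1L] && u <= range[2L])
  }
  repeat {
    st <- in_range(ids)
    if (st$ok)
      return(new_top_hit_set(vs$target_id, ids, st$u, iter, seed))
    if (iter == 0L && nrow(X) < range[2L])
      eo_stop(sprintf("need at least %d ligands, got %d", range[2L], nrow(X)),
              "insufficient_input")
    if (st$u < range[1L]) break  # cannot recover by clustering; trim path
    if (iter >= max_iter)
      eo_stop("successive k-means did not converge to the target range",
              "non_convergence", data = list(ligand_ids = ids,
                                             iterations = iter))
    iter <- iter + 1L
    Xc <- standardize_columns(X[ids, , drop = FALSE])
    rownames(Xc) <- ids
    if (length(ids) <= k) break  # too few rows to cluster further
    km <- with_seed(seed + iter,
                    stats::kmeans(Xc, centers = k, nstart = 10L,
                                  iter.max = 100L))
    quality <- switch(strategy,
                      centroid_mean = rowMeans(km$centers),
                      worst_dimension = apply(km$centers, 1L, min))
    best <- which.max(quality)
    candidate <- ids[km$cluster == best]
    cu <- collapse_enantiomers(candidate, lib)$unique_count
    if (cu < range[1L]) break  # overshoot: revert to `ids`, trim below
    ids <- candidate
  }
  # revert-and-trim: order current set by mean rank of standardized goodness,
  # keep ligands until range[2] unique (collapsed) ligands are reached
  Xc <- standardize_columns(X[ids, , drop = FALSE])
  rownames(Xc) <- ids
  R <- apply(-Xc, 2L, rank, ties.method = "average")
  ord <- order(rowMeans(R), ids)
  kept <- character()
  for (id in ids[ord]) {
    trial <- c(kept, id)
    if (collapse_enantiomers(trial, lib)$unique_count > range[2L]) break
    kept <- trial
  }
  u <- collapse_enantiomers(kept, lib)$unique_count
  new_top_hit_set(vs$target_id, kept, u, iter, seed)
}

new_top_hit_set <- function(target_id, ligand_ids, unique_count, iterations,
                            seed) {
  structure(list(target_id = target_id, ligand_ids = ligand_ids,
                 unique_count = unique_count, iterations = iterations,
                 seed = seed),
            class = "top_hit_set")
}

#' @export
print.top_hit_set <- function(x, ...) {
  cat(sprintf("<top_hit_set %s: %d ligands (%d unique), %d iteration(s)>\n",
              x$target_id, length(x$ligand_ids), x$unique_count,
              x$iterations))
  invisible(x)
}

#' Select the top fraction of ligands by mean rank
#'
#' The simpler selector: the top `ceiling(fraction * N)` ligands of a target
#' by mean rank over the selected functions (e.g. the 1% top-scored
#' ligands).
#'
#' @inheritParams rank_ligands
#' @param fraction screened fraction in (0, 1].
#' @return A `top_hit_set` (iterations 0, seed NA).
#' @export
top_fraction_hits <- function(agg, target_id, fraction = 0.01,
                              function_ids = NULL, lib = NULL) {
  if (fraction <= 0 || fraction > 1)
    eo_stop("fraction must be in (0, 1]", "validation_error")
  rk <- rank_ligands(agg, target_id, function_ids)
  n <- ceiling(fraction * nrow(rk))
  ids <- rk$ligand_id[seq_len(n)]
  u <- if (is.null(lib)) length(ids) else
    collapse_enantiomers(ids, lib)$unique_count
  new_top_hit_set(target_id, ids, u, 0L, NA_integer_)
}

#' Pool per-target hit sets into one unique ligand list
#'
#' Union over targets in input order, duplicates removed by
#' `canonical_key`.
#'
#' @param hit_sets list of `top_hit_set`.
#' @param lib a [ligand_library()].
#' @return character vector of pooled ligand ids.
#' @export
pool_hits <- function(hit_sets, lib) {
  if (!length(hit_sets)) eo_stop("no hit sets to pool", "empty_input")
  ids <- unique(unlist(lapply(hit_sets, `[[`, "ligand_ids")))
  keys <- subset_library(lib, ids)$ligands$canonical_key
  ids[!duplicated(keys)]
}
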