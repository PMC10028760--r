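#' Cluster-by-target association matrices
#'
#' Matrix 1 relates archetype clusters to targets from the cluster's point
#' of view: cell (c, t) is the fraction of cluster c's members that are top
#' hits for target t — the probability that a compound of the cluster is
#' high-scored for the target. Matrix 2 takes the target's point of view:
#' cell (c, t) is the fraction of target t's top hits that fall in cluster
#' c, so each column partitions the target's hits and sums to one.
#'
#' @param hit_sets list of `top_hit_set`, one per target; every hit must be
#'   clustered.
#' @param clustering an [hierarchical_cluster()] result over the pooled
#'   hits.
#' @return A `cluster_target_matrix` (cluster x target) with attribute
#'   `kind`.
#' @export
build_matrix1 <- function(hit_sets, clustering) {
  counts <- hit_cluster_counts(hit_sets, clustering)
  size <- table(clustering$labels)[rownames(counts)]
  M <- sweep(counts, 1L, as.numeric(size), `/`)
  structure(M, kind = "matrix1", class = c("cluster_target_matrix", class(M)))
}

#' @rdname build_matrix1
#' @export
build_matrix2 <- function(hit_sets, clustering) {
  counts <- hit_cluster_counts(hit_sets, clustering)
  n_hits <- colSums(counts)
  if (any(n_hits == 0))
    eo_stop("target with zero clustered hits", "validation_error")
  M <- sweep(counts, 2L, n_hits, `/`)
  structure(M, kind = "matrix2", class = c("cluster_target_matrix", class(M)))
}

hit_cluster_counts <- function(hit_sets, clustering) {
  stopifnot(inherits(clustering, "archetype_clustering"))
  cls <- sort(unique(clustering$labels))
  targets <- vapply(hit_sets, `[[`, character(1), "target_id")
  counts <- matrix(0, length(cls), length(targets),
                   dimnames = list(cls, targets))
  for (hs in hit_sets) {
    unknown <- setdiff(hs$ligand_ids, names(clustering$labels))
    if (length(unknown))
      eo_stop(sprintf("unclustered hit(s) for target %s: %s", hs$target_id,
                      paste(utils::head(unknown, 5L), collapse = ", ")),
              "consistency_error")
    tb <- table(clustering$labels[hs$ligand_ids])
    counts[names(tb), hs$target_id] <- as.numeric(tb)
  }
  counts
}

#' Compound-by-target scores from a similarity and an association matrix
#'
#' Standard matrix product `S %*% M` of a compound x cluster similarity
#' matrix (EPNMCS proximity or BDSTFL membership) with a cluster x target
#' association matrix (Matrix 1 or Matrix 2), cluster ids aligned by name.
#'
#' @param S a [epnmcs()] or [bdstfl()] matrix (compound x cluster).
#' @param M a [build_matrix1()] / [build_matrix2()] matrix (cluster x
#'   target).
#' @return A `compound_target_score` matrix with a `provenance` attribute.
#' @export
compound_target_scores <- function(S, M) {
  if (!setequal(colnames(S), rownames(M)))
    eo_stop("cluster ids of the similarity and association matrices differ",
            "alignment_error")
  M <- M[colnames(S), , drop = FALSE]
  out <- unclass(S) %*% unclass(M)
  prov <- paste(class(S)[1L], attr(M, "kind") %||% "matrix", sep = " x ")
  structure(out, provenance = prov,
            class = c("compound_target_score", class(out)))
}

# melt two aligned compound x target matrices (or accept paired vectors)
paired_vectors <- function(scores, dock_rank) {
  if (is.matrix(scores) || inherits(scores, "compound_target_score")) {
    scores <- unclass(scores)
    dock_rank <- unclass(dock_rank)
    if (!identical(dim(scores), dim(dock_rank)))
      dock_rank <- dock_rank[rownames(scores), colnames(scores)]
    list(score = as.vector(scores), rank = as.vector(dock_rank))
  } else {
    if (length(scores) != length(dock_rank))
      eo_stop("scores and ranks must be paired", "validation_error")
    list(score = as.numeric(scores), rank = as.numeric(dock_rank))
  }
}

#' Correlation validation of similarity-derived scores against docking rank
#'
#' Ordinary least squares of mean docking rank (smaller = better) on the
#' compound-by-target similarity score, over all (compound, target) pairs.
#' Reports the squared Pearson correlation, the regression F statistic
#' `F = (n - 2) r^2 / (1 - r^2)`, and the slope sign (a negative slope
#' means higher proximity predicts better, i.e. smaller, rank).
#'
#' @param scores compound x target score matrix (or numeric vector).
#' @param dock_rank matching matrix of mean docking ranks (or vector).
#' @return list with `r2`, `F`, `n`, `slope_sign`, `p_value`.
#' @export
rank_correlation_validation <- function(scores, dock_rank) {
  pv <- paired_vectors(scores, dock_rank)
  ok <- is.finite(pv$score) & is.finite(pv$rank)
  x <- pv$score[ok]; y <- pv$rank[ok]
  n <- length(x)
  if (n < 3L) eo_stop("need at least 3 paired observations",
                      "validation_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    eo_stop("zero variance in scores or ranks: degenerate regression",
            "degenerate_regression")
  r <- stats::cor(x, y)
  r2 <- r^2
  Fstat <- (n - 2) * r2 / (1 - r2)
  list(r2 = r2, F = Fstat, n = n, slope_sign = sign(r),
       p_value = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE))
}

#' Binned ANOVA with Tukey post hoc letter groups
#'
#' The similarity-score axis is split into half-open categorical classes
#' `[k w, (k+1) w)` of width `bin_width`; a one-way ANOVA of docking rank on
#' bin is followed by Tukey HSD, and bins are annotated with a compact
#' letter display (bins sharing a letter are not significantly different at
#' `alpha`). Bins with fewer than 2 observations are excluded with a
#' warning.
#'
#' @inheritParams rank_correlation_validation
#' @param bin_width class width on the score axis (default 0.1).
#' @param alpha family-wise significance level for the Tukey comparisons.
#' @return list with `table` (bin, n, mean_rank, letters, ordered from the
#'   best — smallest — mean rank), `F`, `p_value`, `df`.
#' @export
binned_anova_tukey <- function(scores, dock_rank, bin_width = 0.1,
                               alpha = 0.05) {
  pv <- paired_vectors(scores, dock_rank)
  bin <- floor(pv$score / bin_width)
  tab <- table(bin)
  small <- names(tab)[tab < 2L]
  if (length(small))
    eo_warn(sprintf("excluding %d bin(s) with fewer than 2 observations",
                    length(small)), "sparse_bin_warning")
  keep <- !(as.character(bin) %in% small)
  bin <- bin[keep]; y <- pv$rank[keep]
  bins <- sort(unique(bin))
  if (length(bins) < 2L)
    eo_stop("fewer than 2 usable bins", "insufficient_bins")
  # safe level labels so Tukey pair names split unambiguously (bins can be
  # negative)
  f <- factor(bin, levels = bins, labels = paste0("b", seq_along(bins)))
  if (stats::sd(y) == 0) {
    eo_warn("all observations identical: F undefined", "degenerate_anova_warning")
    tb <- data.frame(bin = bins * bin_width, n = as.integer(table(f)),
                     mean_rank = tapply(y, f, mean), letters = "a",
                     row.names = NULL)
    return(list(table = tb, F = NA_real_, p_value = NA_real_, df = NULL))
  }
  fit <- stats::aov(y ~ f)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$f
  # p-adjusted matrix over bin pairs
  lv <- levels(f)
  padj <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  padj[pairs] <- tk[, "p adj"]
  padj[pairs[, c(2L, 1L), drop = FALSE]] <- tk[, "p adj"]
  letters <- compact_letters(stats::setNames(as.numeric(tapply(y, f, mean)),
                                             lv),
                             padj, alpha)
  tb <- data.frame(bin = bins * bin_width, n = as.integer(table(f)),
                   mean_rank = as.numeric(tapply(y, f, mean)),
                   letters = letters[lv], row.names = NULL)
  tb <- tb[order(tb$mean_rank), ]
  rownames(tb) <- NULL
  list(table = tb, F = an[1L, "F value"], p_value = an[1L, "Pr(>F)"],
       df = an$Df)
}

# compact letter display: groups = clique cover of the "not significantly
# different" graph; letters assigned from the best (smallest) mean onward
compact_letters <- function(means, padj, alpha) {
  lv <- names(means)
  nsd <- padj >= alpha
  diag(nsd) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  cliques <- lapply(cliques, function(cl) lv[as.integer(cl)])
  # order cliques by their best member mean so 'a' marks the best group
  cliques <- cliques[order(vapply(cliques, function(cl) min(means[cl]),
                                  numeric(1)))]
  out <- stats::setNames(rep("", length(lv)), lv)
  for (i in seq_along(cliques))
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  out
}

#' Binary likelihood matrix from compound-by-target scores
#'
#' A compound is flagged as having a probable signature for a target when
#' its product score strictly exceeds `threshold` (default 3.01, the cut
#' separating the high-docking-score Tukey class).
#'
#' @param scores a [compound_target_scores()] matrix.
#' @param threshold cut value; strictly greater scores map to 1.
#' @return A `likelihood_matrix` of 0/1 values with attribute `threshold`.
#' @export
build_likelihood <- function(scores, threshold = 3.01) {
  stopifnot_scalar_number(threshold, "threshold")
  if (any(!is.finite(unclass(scores))))
    eo_stop("scores must be finite", "validation_error")
  L <- (unclass(scores) > threshold) * 1
  structure(L, threshold = threshold,
            class = c("likelihood_matrix", class(L)))
}
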