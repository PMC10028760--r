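#' Hierarchical clustering of ligands on a Tanimoto distance matrix
#'
#' Agglomerative clustering of chemically similar compounds: the tree is
#' built on the pairwise Tanimoto distance and cut at a distance `cutoff`.
#' Singletons are permitted; cluster ids (`C01`, `C02`, ...) are assigned in
#' order of first member appearance.
#'
#' @param distmat square symmetric distance matrix with zero diagonal and
#'   ligand ids as dimnames.
#' @param linkage `"average"` (UPGMA, the default for Tanimoto distances),
#'   `"complete"`, `"single"`, or `"ward"` (Ward on squared distances,
#'   `ward.D2`).
#' @param cutoff tree-cut height.
#' @return An `archetype_clustering`: list with `ligand_ids`, `labels`
#'   (named cluster ids), `linkage`, `cutoff`, `n_clusters`, and the
#'   underlying `hclust` tree.
#' @export
hierarchical_cluster <- function(distmat,
                                 linkage = c("average", "complete", "single",
                                             "ward"),
                                 cutoff) {
  linkage <- match.arg(linkage)
  validate_distmat(distmat)
  stopifnot_scalar_number(cutoff, "cutoff")
  ids <- rownames(distmat)
  method <- if (linkage == "ward") "ward.D2" else linkage
  if (length(ids) == 1L) {
    labels <- stats::setNames("C01", ids)
    return(structure(list(ligand_ids = ids, labels = labels,
                          linkage = linkage, cutoff = cutoff, n_clusters = 1L,
                          tree = NULL),
                     class = "archetype_clustering"))
  }
  tree <- stats::hclust(stats::as.dist(distmat), method = method)
  raw <- stats::cutree(tree, h = cutoff)
  labels <- relabel_first_appearance(raw[ids])
  structure(list(ligand_ids = ids, labels = labels, linkage = linkage,
                 cutoff = cutoff, n_clusters = length(unique(labels)),
                 tree = tree),
            class = "archetype_clustering")
}

validate_distmat <- function(d) {
  if (!is.matrix(d) || nrow(d) == 0L)
    eo_stop("distance matrix must be a non-empty matrix", "empty_input")
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    eo_stop("distance matrix must be square and symmetric",
            "validation_error")
  if (any(abs(diag(d)) > 1e-12))
    eo_stop("distance matrix must have a zero diagonal", "validation_error")
  if (is.null(rownames(d)))
    eo_stop("distance matrix needs ligand ids as dimnames",
            "validation_error")
  invisible(TRUE)
}

relabel_first_appearance <- function(raw) {
  first <- unique(raw)
  new <- stats::setNames(sprintf("C%02d", seq_along(first)), first)
  stats::setNames(new[as.character(raw)], names(raw))
}

#' @export
print.archetype_clustering <- function(x, ...) {
  cat(sprintf("<archetype_clustering: %d ligands in %d cluster(s), %s linkage, cutoff %.3g>\n",
              length(x$ligand_ids), x$n_clusters, x$linkage, x$cutoff))
  invisible(x)
}

#' Choose a tree-cut height by silhouette maximization
#'
#' Evaluates each candidate cutoff on a grid and returns the one maximizing
#' the mean silhouette width of the induced partition (computed on the
#' distance matrix itself); ties go to the smaller cutoff. Cutoffs whose
#' partition is trivial (one cluster, or all singletons) are skipped; if
#' every candidate is trivial a no-structure error is raised.
#'
#' @inheritParams hierarchical_cluster
#' @param grid candidate cutoffs in (0, 1).
#' @return list with `cutoff`, `silhouette` (mean width at the chosen
#'   cutoff), and `profile` (data.frame cutoff, n_clusters, mean_silhouette).
#' @export
choose_cutoff <- function(distmat, linkage = "average",
                          grid = seq(0.05, 0.95, by = 0.05)) {
  validate_distmat(distmat)
  if (any(grid <= 0 | grid >= 1))
    eo_stop("cutoff grid must lie in (0, 1)", "validation_error")
  n <- nrow(distmat)
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(stats::as.dist(distmat), method = method)
  prof <- data.frame(cutoff = grid, n_clusters = NA_integer_,
                     mean_silhouette = NA_real_)
  for (i in seq_along(grid)) {
    cl <- stats::cutree(tree, h = grid[i])
    kk <- length(unique(cl))
    prof$n_clusters[i] <- kk
    if (kk <= 1L || kk >= n) next
    sil <- cluster::silhouette(cl, dmatrix = distmat)
    prof$mean_silhouette[i] <- mean(sil[, "sil_width"])
  }
  usable <- which(!is.na(prof$mean_silhouette))
  if (!length(usable))
    eo_stop("no non-trivial partition on the cutoff grid (no structure)",
            "no_structure")
  best <- usable[which.max(prof$mean_silhouette[usable])]  # ties: smaller cutoff
  list(cutoff = prof$cutoff[best], silhouette = prof$mean_silhouette[best],
       profile = prof)
}

#' Cluster centroids in z-scored descriptor space
#'
#' The centroid of a cluster is the arithmetic mean of its members'
#' descriptor vectors.
#'
#' @param clustering an [hierarchical_cluster()] result.
#' @param ztable z-scored descriptor matrix (compounds x descriptors,
#'   rownames = ids) covering every clustered ligand.
#' @return matrix cluster x descriptor.
#' @export
compute_centroids <- function(clustering, ztable) {
  stopifnot(inherits(clustering, "archetype_clustering"))
  ztable <- as_descriptor_matrix(ztable)
  miss <- setdiff(clustering$ligand_ids, rownames(ztable))
  if (length(miss))
    eo_stop(sprintf("missing descriptor row(s): %s",
                    paste(utils::head(miss, 5L), collapse = ", ")),
            "missing_descriptor")
  cls <- sort(unique(clustering$labels))
  out <- t(vapply(cls, function(cl) {
    members <- names(clustering$labels)[clustering$labels == cl]
    colMeans(ztable[members, , drop = FALSE])
  }, numeric(ncol(ztable))))
  rownames(out) <- cls
  out
}

#' Allocate compounds to the nearest archetype centroid
#'
#' One k-means assignment step with frozen centroids: each compound goes to
#' the cluster whose centroid is nearest in Euclidean distance (ties to the
#' lowest cluster id). Centroids are not updated, so the archetypes stay
#' anchored to the top-hit definition.
#'
#' @param ztable z-scored descriptor rows for the compounds to allocate.
#' @param centroids matrix from [compute_centroids()].
#' @return A `cluster_allocation` data.frame (compound_id, cluster_id,
#'   distance).
#' @export
allocate_compounds <- function(ztable, centroids) {
  ztable <- as_descriptor_matrix(ztable)
  if (ncol(ztable) != ncol(centroids))
    eo_stop("descriptor dimensions do not match the centroids",
            "validation_error")
  D <- euclidean_cross_distance(ztable, centroids)
  best <- apply(D, 1L, which.min)  # which.min takes the first (lowest id) tie
  structure(data.frame(compound_id = rownames(ztable),
                       cluster_id = rownames(centroids)[best],
                       distance = D[cbind(seq_len(nrow(D)), best)],
                       stringsAsFactors = FALSE),
            class = c("cluster_allocation", "data.frame"))
}

# row-by-row Euclidean distances between two point sets
euclidean_cross_distance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  dimnames(d) <- list(rownames(A), rownames(B))
  d
}

#' Export the clustering dendrogram as Newick text
#'
#' @param clustering an [hierarchical_cluster()] result with at least two
#'   leaves.
#' @param path optional file to write to.
#' @return The Newick string, invisibly when written to a file.
#' @export
as_newick <- function(clustering, path = NULL) {
  stopifnot(inherits(clustering, "archetype_clustering"))
  if (is.null(clustering$tree))
    eo_stop("single-leaf clustering has no dendrogram", "validation_error")
  txt <- ape::write.tree(ape::as.phylo(clustering$tree))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
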