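#' Molecular descriptor tables and z-scoring
#'
#' Descriptors (molecular weight, logP-like terms, polar surface area,
#' counts, ...) are accepted as any precomputed numeric table; descriptor
#' identity is configuration, not contract. Each column is standardized to
#' `z = (value - column mean) / column sd` so heterogeneous descriptors
#' become comparable; constant columns carry no information and are dropped
#' with a warning.
#'
#' @param x numeric matrix or data.frame of raw descriptor values
#'   (compounds x descriptors), rownames = compound ids (or a first `id`
#'   column in a data.frame).
#' @param ddof degrees-of-freedom correction for the column sd (1 = sample
#'   sd, the default).
#' @return `zscore_descriptors` returns a `descriptor_table`: list with
#'   `raw` and `zscored` matrices.
#' @export
zscore_descriptors <- function(x, ddof = 1) {
  M <- as_descriptor_matrix(x)
  if (nrow(M) < 2L)
    eo_stop("z-scoring needs at least two compounds", "validation_error")
  sds <- apply(M, 2L, sd_ddof, ddof = ddof)
  constant <- !is.finite(sds) | sds == 0
  if (all(constant))
    eo_stop("all descriptor columns are constant: no information",
            "no_information")
  if (any(constant)) {
    eo_warn(sprintf("dropping constant descriptor column(s): %s",
                    paste(colnames(M)[constant], collapse = ", ")),
            "constant_descriptor_warning")
    M <- M[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  Z <- sweep(sweep(M, 2L, colMeans(M)), 2L, sds, `/`)
  structure(list(raw = M, zscored = Z), class = "descriptor_table")
}

# coerce matrix / data.frame (optionally with an id column) / descriptor_table
as_descriptor_matrix <- function(x, zscored = TRUE) {
  if (inherits(x, "descriptor_table"))
    return(if (zscored) x$zscored else x$raw)
  if (is.data.frame(x)) {
    if (!is.null(x[["id"]]) || !is.null(x[["compound_id"]])) {
      idcol <- if (!is.null(x[["compound_id"]])) "compound_id" else "id"
      ids <- as.character(x[[idcol]])
      x <- x[setdiff(names(x), idcol)]
      x <- as.matrix(x)
      rownames(x) <- ids
    } else x <- as.matrix(x)
  }
  if (!is.numeric(x)) eo_stop("descriptor values must be numeric",
                              "validation_error")
  if (anyNA(x)) eo_stop("descriptor table contains missing cells",
                        "validation_error")
  if (is.null(rownames(x)))
    eo_stop("descriptor rows must be named by compound id",
            "validation_error")
  x
}

#' Read a descriptor table from CSV
#'
#' First column is the compound id; remaining columns are numeric
#' descriptors.
#'
#' @param path file path.
#' @return numeric matrix with compound ids as rownames.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  M <- as.matrix(df[-1L])
  rownames(M) <- ids
  as_descriptor_matrix(M)
}

#' Euclidean proximity matrix (EPNMCS)
#'
#' For each compound and each archetype centroid, the Euclidean distance in
#' z-scored descriptor space is computed; all distances are divided by the
#' largest distance obtained so they fall in \[0, 1\], and proximity is one
#' minus that normalized distance. The normalizing constant is recorded so a
#' later batch can be scored on the same scale (`normalizing_constant`
#' argument).
#'
#' @param ztable z-scored descriptor rows (matrix or `descriptor_table`).
#' @param centroids matrix from [compute_centroids()].
#' @param normalizing_constant optional frozen maximum distance from an
#'   earlier batch; default: the maximum over all (compound, centroid) pairs
#'   of this computation.
#' @return A `proximity_matrix`: compound x cluster matrix in \[0, 1\] with
#'   attribute `normalizing_constant`.
#' @export
epnmcs <- function(ztable, centroids, normalizing_constant = NULL) {
  Z <- as_descriptor_matrix(ztable)
  if (ncol(Z) != ncol(centroids))
    eo_stop("descriptor dimensions do not match the centroids",
            "validation_error")
  D <- euclidean_cross_distance(Z, centroids)
  dmax <- normalizing_constant %||% max(D)
  if (dmax == 0)
    eo_stop("all compounds coincide with all centroids: degenerate geometry",
            "degenerate_geometry")
  P <- 1 - D / dmax
  structure(P, normalizing_constant = dmax,
            class = c("proximity_matrix", class(P)))
}

#' Fuzzy Tanimoto degrees of belonging (BDSTFL)
#'
#' Membership of a compound in an archetype cluster, derived from its
#' Tanimoto similarities to the cluster's members: the raw membership is the
#' `stat` (mean or max) of those similarities, and rows are rescaled to sum
#' to one so each row is a fuzzy degree-of-belonging profile. A compound
#' with zero similarity to every cluster gets a uniform row with a warning.
#'
#' @param lib a [ligand_library()] with fingerprints for the compounds and
#'   all cluster members.
#' @param clustering an [hierarchical_cluster()] result over the cluster
#'   members.
#' @param compounds ids of the compounds to profile.
#' @param stat `"mean"` (mean-linkage membership, default) or `"max"`.
#' @param normalize rescale rows to sum 1 (default TRUE).
#' @return A `membership_matrix`: compound x cluster matrix in \[0, 1\].
#' @export
bdstfl <- function(lib, clustering, compounds, stat = c("mean", "max"),
                   normalize = TRUE) {
  stat <- match.arg(stat)
  stopifnot(inherits(clustering, "archetype_clustering"))
  members <- names(clustering$labels)
  all_ids <- union(compounds, members)
  if (!all(all_ids %in% names(lib$fingerprints)))
    eo_stop("fingerprints required for all compounds and cluster members",
            "validation_error")
  cls <- sort(unique(clustering$labels))
  if (any(!cls %in% clustering$labels))
    eo_stop("empty cluster in labels", "validation_error")
  B <- fingerprint_bit_matrix(lib$fingerprints[all_ids])
  sim <- tanimoto_similarity_matrix(B)
  M <- vapply(cls, function(cl) {
    mem <- members[clustering$labels == cl]
    s <- sim[compounds, mem, drop = FALSE]
    if (stat == "mean") rowMeans(s) else apply(s, 1L, max)
  }, numeric(length(compounds)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(compounds),
                                   dimnames = list(compounds, cls))
  dimnames(M) <- list(compounds, cls)
  if (normalize) {
    rs <- rowSums(M)
    zero <- rs == 0
    if (any(zero)) {
      eo_warn(sprintf(
        "%d compound(s) with zero similarity to every cluster: uniform membership assigned",
        sum(zero)), "zero_membership_warning")
      M[zero, ] <- 1 / length(cls)
      rs[zero] <- 1
    }
    M <- M / rs
  }
  structure(M, stat = stat, normalized = normalize,
            class = c("membership_matrix", class(M)))
}

#' Write a named matrix as headered CSV
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @param rowname_header header for the rowname column.
#' @export
write_matrix_csv <- function(m, path, rowname_header = "id") {
  df <- data.frame(rn = rownames(m), as.data.frame(unclass(m),
                                                   check.names = FALSE))
  names(df)[1L] <- rowname_header
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
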