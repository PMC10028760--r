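#' Molecular fingerprints as fixed-length bitsets
#'
#' A fingerprint is a fixed-length bit vector under a named scheme
#' (e.g. a hashed circular substructure fingerprint, radius 2, 2048 bits).
#' All pairwise comparisons require matching `n_bits` and `scheme_id`.
#'
#' @param bits logical or 0/1 integer vector of bit values.
#' @param scheme_id string naming the fingerprint scheme.
#' @return An object of class `eo_fingerprint`.
#' @examples
#' a <- fingerprint(c(1, 1, 0), "demo")
#' b <- fingerprint(c(0, 1, 1), "demo")
#' tanimoto_similarity(a, b)  # 1/3
#' @export
fingerprint <- function(bits, scheme_id = "fp") {
  if (is.numeric(bits)) {
    if (any(!bits %in% c(0, 1)))
      eo_stop("fingerprint bits must be 0/1 or logical", "validation_error")
    bits <- bits == 1
  }
  if (!is.logical(bits) || length(bits) < 1L || anyNA(bits))
    eo_stop("fingerprint bits must be a non-empty logical vector without NA",
            "validation_error")
  structure(list(bits = bits, n_bits = length(bits),
                 scheme_id = as.character(scheme_id)),
            class = "eo_fingerprint")
}

#' @export
print.eo_fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %s, %d bits, %d set>\n",
              x$scheme_id, x$n_bits, sum(x$bits)))
  invisible(x)
}

check_compatible <- function(a, b) {
  if (!inherits(a, "eo_fingerprint") || !inherits(b, "eo_fingerprint"))
    eo_stop("both arguments must be fingerprints", "validation_error")
  if (a$n_bits != b$n_bits || a$scheme_id != b$scheme_id)
    eo_stop(sprintf(
      "incompatible fingerprints: %s/%d bits vs %s/%d bits",
      a$scheme_id, a$n_bits, b$scheme_id, b$n_bits),
      "incompatible_fingerprint")
  invisible(TRUE)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A AND B| / |A OR B|` over the set bits. Two all-zero fingerprints are
#' defined as identical (similarity 1) with a warning, since they encode the
#' same absence of features.
#'
#' @param a,b `eo_fingerprint` objects sharing `n_bits` and `scheme_id`.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto_similarity <- function(a, b) {
  check_compatible(a, b)
  inter <- sum(a$bits & b$bits)
  union <- sum(a$bits | b$bits)
  if (union == 0L) {
    eo_warn("Tanimoto of two empty fingerprints defined as 1.0",
            "empty_fingerprint_warning")
    return(1.0)
  }
  inter / union
}

# Bit matrix (ligand x bit, 0/1) from a list of compatible fingerprints
fingerprint_bit_matrix <- function(fps) {
  if (length(fps) == 0L) eo_stop("empty fingerprint set", "empty_input")
  n_bits <- vapply(fps, function(f) f$n_bits, integer(1))
  scheme <- vapply(fps, function(f) f$scheme_id, character(1))
  if (length(unique(n_bits)) != 1L || length(unique(scheme)) != 1L)
    eo_stop("fingerprints differ in n_bits or scheme", "incompatible_fingerprint")
  B <- do.call(rbind, lapply(fps, function(f) as.integer(f$bits)))
  rownames(B) <- names(fps)
  B
}

# Pairwise Tanimoto similarity for a 0/1 bit matrix, vectorized
tanimoto_similarity_matrix <- function(B) {
  inter <- tcrossprod(B)
  counts <- rowSums(B)
  union <- outer(counts, counts, `+`) - inter
  sim <- ifelse(union == 0, 1, inter / union)
  diag(sim) <- 1
  sim
}

#' Pairwise Tanimoto distance matrix for a ligand library
#'
#' Entry (i, j) is `1 - tanimoto_similarity(i, j)`; the diagonal is zero.
#'
#' @param lib a [ligand_library()].
#' @return Symmetric numeric matrix with ligand ids as dimnames.
#' @export
tanimoto_distance_matrix <- function(lib) {
  stopifnot(inherits(lib, "ligand_library"))
  if (nrow(lib$ligands) == 0L) eo_stop("empty ligand library", "empty_input")
  B <- fingerprint_bit_matrix(lib$fingerprints[lib$ligands$id])
  d <- 1 - tanimoto_similarity_matrix(B)
  diag(d) <- 0
  d
}

#' Read fingerprints from a hex sidecar file
#'
#' Delimited text with columns `id`, `n_bits`, `hex`; the hex string encodes
#' the bitset most-significant-nibble first and is left-padded to
#' `ceiling(n_bits / 4)` characters.
#'
#' @param path file path.
#' @param scheme_id scheme label attached to each fingerprint.
#' @return Named list of `eo_fingerprint`.
#' @export
read_fingerprints <- function(path, scheme_id = "fp") {
  df <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("id", "n_bits", "hex")
  if (!all(need %in% names(df)))
    eo_stop("fingerprint file needs columns id, n_bits, hex", "format_error")
  fps <- Map(function(nb, hx) fingerprint(hex_to_bits(hx, nb), scheme_id),
             df$n_bits, df$hex)
  names(fps) <- df$id
  fps
}

#' @rdname read_fingerprints
#' @param fps named list of fingerprints to write.
#' @export
write_fingerprints <- function(fps, path) {
  df <- data.frame(
    id = names(fps),
    n_bits = vapply(fps, function(f) f$n_bits, integer(1)),
    hex = vapply(fps, function(f) bits_to_hex(f$bits), character(1)))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

hex_to_bits <- function(hex, n_bits) {
  nib <- strtoi(strsplit(tolower(hex), "")[[1]], base = 16L)
  if (anyNA(nib)) eo_stop("invalid hex fingerprint string", "format_error")
  bits <- as.vector(vapply(nib, function(v) as.logical(bitwAnd(v, c(8L, 4L, 2L, 1L))),
                           logical(4)))
  if (length(bits) < n_bits)
    eo_stop("hex string shorter than n_bits", "format_error")
  utils::tail(bits, n_bits)
}

bits_to_hex <- function(bits) {
  pad <- (-length(bits)) %% 4
  b <- c(rep(FALSE, pad), bits)
  m <- matrix(as.integer(b), nrow = 4)
  paste(sprintf("%x", as.integer(colSums(m * c(8L, 4L, 2L, 1L)))), collapse = "")
}
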