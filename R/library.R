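#' Ligand libraries
#'
#' A ligand library holds ligand identities (id, SMILES, canonical keys,
#' source) together with one fingerprint per ligand. `canonical_key` is a
#' stereo-aware canonical structure string; `flat_key` strips stereochemistry
#' so enantiomer pairs share a key ("unique ligands, not considering
#' enantiomers").
#'
#' Canonicalization is pluggable. The `"identity"` backend uses the SMILES
#' text itself (flat key: stereo markers `@`, `/`, `\` removed), so the
#' library never requires a chemistry toolkit; the `"openbabel"` backend
#' canonicalizes through Open Babel (via \pkg{ChemmineOB}) when available.
#' Explicit `canonical_keys` / `flat_keys` always win over any backend.
#'
#' @param ids character vector of unique ligand ids.
#' @param smiles SMILES strings, one per id.
#' @param fingerprints named list of [fingerprint()]s keyed by id (optional at
#'   construction; required by fingerprint-based operations).
#' @param source `"database"` or `"chromatography"`, recycled.
#' @param canonical_keys,flat_keys optional explicit keys, one per id.
#' @param backend `"identity"` or `"openbabel"`.
#' @return An object of class `ligand_library` with elements `ligands`
#'   (data.frame: id, smiles, canonical_key, flat_key, source) and
#'   `fingerprints` (named list).
#' @export
ligand_library <- function(ids, smiles = ids, fingerprints = NULL,
                           source = "database",
                           canonical_keys = NULL, flat_keys = NULL,
                           backend = c("identity", "openbabel")) {
  backend <- match.arg(backend)
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    eo_stop("ligand ids must be unique within a library", "validation_error")
  if (length(smiles) != length(ids))
    eo_stop("one SMILES per id required", "validation_error")
  source <- rep_len(match.arg(source, c("database", "chromatography"),
                              several.ok = TRUE), length(ids))
  if (is.null(canonical_keys))
    canonical_keys <- canonicalize_smiles(smiles, backend, flat = FALSE)
  if (is.null(flat_keys))
    flat_keys <- canonicalize_smiles(smiles, backend, flat = TRUE)
  if (!is.null(fingerprints)) {
    missing <- setdiff(names(fingerprints), ids)
    if (length(missing))
      eo_stop(sprintf("fingerprint keys without matching ligand: %s",
                      paste(missing, collapse = ", ")), "validation_error")
  }
  structure(list(
    ligands = data.frame(id = ids, smiles = as.character(smiles),
                         canonical_key = canonical_keys,
                         flat_key = flat_keys, source = source,
                         stringsAsFactors = FALSE),
    fingerprints = fingerprints %||% list()),
    class = "ligand_library")
}

#' @export
print.ligand_library <- function(x, ...) {
  cat(sprintf("<ligand_library: %d ligands, %d fingerprints>\n",
              nrow(x$ligands), length(x$fingerprints)))
  invisible(x)
}

#' @export
length.ligand_library <- function(x) nrow(x$ligands)

# subset a library by id, preserving order of `ids`
subset_library <- function(lib, ids) {
  idx <- match(ids, lib$ligands$id)
  if (anyNA(idx))
    eo_stop(sprintf("unknown ligand id(s): %s",
                    paste(ids[is.na(idx)], collapse = ", ")), "missing_ligand")
  out <- lib
  out$ligands <- lib$ligands[idx, , drop = FALSE]
  rownames(out$ligands) <- NULL
  out$fingerprints <- lib$fingerprints[intersect(ids, names(lib$fingerprints))]
  out
}

strip_stereo <- function(smiles) gsub("[@/\\\\]", "", smiles)

canonicalize_smiles <- function(smiles, backend, flat) {
  if (flat) smiles <- strip_stereo(smiles)
  if (backend == "identity") return(as.character(smiles))
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    eo_stop("openbabel backend requires the ChemmineOB package",
            "backend_unavailable")
  vapply(smiles, function(s) {
    out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))
    sub("[\t\n ].*$", "", out)
  }, character(1), USE.NAMES = FALSE)
}

#' Remove ligands with Tanimoto similarity exactly 1
#'
#' Every pair at similarity 1.0 is collapsed to the first occurrence in input
#' order; all discarded pairs are reported as (kept_id, dropped_id).
#'
#' @param lib a [ligand_library()] with fingerprints for all ligands.
#' @param tol equality tolerance on the similarity (exact bit identity at the
#'   default).
#' @return list with `kept` (deduplicated library) and `dropped`
#'   (data.frame kept_id, dropped_id).
#' @export
deduplicate <- function(lib, tol = 1e-12) {
  stopifnot(inherits(lib, "ligand_library"))
  ids <- lib$ligands$id
  if (!all(ids %in% names(lib$fingerprints)))
    eo_stop("fingerprints required for all ligands", "validation_error")
  if (length(ids) <= 1L)
    return(list(kept = lib,
                dropped = data.frame(kept_id = character(), dropped_id = character())))
  sim <- tanimoto_similarity_matrix(fingerprint_bit_matrix(lib$fingerprints[ids]))
  keep <- rep(TRUE, length(ids))
  kept_id <- dropped_id <- character()
  for (j in seq_along(ids)[-1]) {
    dup <- which(keep[seq_len(j - 1L)] & sim[seq_len(j - 1L), j] >= 1 - tol)
    if (length(dup)) {
      keep[j] <- FALSE
      kept_id <- c(kept_id, ids[dup[1L]])
      dropped_id <- c(dropped_id, ids[j])
    }
  }
  list(kept = subset_library(lib, ids[keep]),
       dropped = data.frame(kept_id = kept_id, dropped_id = dropped_id,
                            stringsAsFactors = FALSE))
}

#' Count ligands collapsing enantiomer pairs
#'
#' Groups the given ids by `flat_key` (stereochemistry-stripped canonical
#' key); enantiomers of one scaffold fall into the same group.
#'
#' @param ids ligand ids to count.
#' @param lib a [ligand_library()] containing them.
#' @return list with `unique_count` and `representatives` (first member of
#'   each group in input order).
#' @export
collapse_enantiomers <- function(ids, lib) {
  stopifnot(inherits(lib, "ligand_library"))
  sub <- subset_library(lib, ids)$ligands
  first <- !duplicated(sub$flat_key)
  list(unique_count = sum(first), representatives = sub$id[first])
}

#' Read a SMILES list
#'
#' Two-column delimited text (id, SMILES); `#` comments and blank lines are
#' ignored.
#'
#' @param path file path.
#' @inheritParams ligand_library
#' @return A [ligand_library()] without fingerprints.
#' @export
read_smiles <- function(path, source = "database",
                        backend = c("identity", "openbabel")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) eo_stop("no SMILES records in file", "empty_input")
  parts <- strsplit(lines, "[,\t ]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    eo_stop(sprintf("malformed SMILES line(s): %s", paste(bad, collapse = ", ")),
            "format_error")
  ligand_library(ids = vapply(parts, `[[`, character(1), 1L),
                 smiles = vapply(parts, `[[`, character(1), 2L),
                 source = source, backend = match.arg(backend))
}
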