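#' Chromatographic composition profiles
#'
#' Per species, the gas-chromatography area fraction of each identified
#' compound. Fractions are proportions; a remainder of unidentified material
#' is allowed, so a species' fractions must sum to at most 1 (within
#' tolerance).
#'
#' @param path CSV with columns `species`, `compound_id`, `fraction`.
#'   Fractions given as percents are auto-detected (any value above 1.5)
#'   and divided by 100 with a message.
#' @return A `chromatogram_set` data.frame (species, compound_id, fraction).
#' @export
read_chromatogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "compound_id", "fraction")
  if (!all(need %in% names(df)))
    eo_stop("chromatogram file needs columns species, compound_id, fraction",
            "format_error")
  chromatogram_set(df)
}

#' @rdname read_chromatogram
#' @param df data.frame with the three chromatogram columns.
#' @export
chromatogram_set <- function(df) {
  df$fraction <- as.numeric(df$fraction)
  if (!nrow(df)) eo_stop("empty chromatogram table", "validation_error")
  if (any(!is.finite(df$fraction)))
    eo_stop("non-numeric fraction values", "validation_error")
  if (any(df$fraction < 0))
    eo_stop("negative area fraction", "validation_error")
  if (any(df$fraction > 1.5)) {
    message("chromatogram fractions look like percents; dividing by 100")
    df$fraction <- df$fraction / 100
  }
  sums <- tapply(df$fraction, df$species, sum)
  if (any(sums > 1 + 1e-6))
    eo_stop(sprintf("species total area fraction exceeds 100%%: %s",
                    paste(names(sums)[sums > 1 + 1e-6], collapse = ", ")),
            "validation_error")
  df <- df[c("species", "compound_id", "fraction")]
  df$species <- as.character(df$species)
  df$compound_id <- as.character(df$compound_id)
  structure(df, class = c("chromatogram_set", "data.frame"))
}

#' Predict per-species essential-oil action profiles
#'
#' The predicted action of a whole essential oil on a target is the
#' composition-weighted sum over its compounds:
#' `value(s, t) = sum_i fraction(s, i) * W(i, t)`, where `W` is the binary
#' likelihood matrix (`weighting = "binary_likelihood"`) or the continuous
#' compound-by-target product score (`"continuous_score"`). Chromatogram
#' compounds absent from `W` are excluded and reported through the
#' `coverage` attribute (matched fraction mass per species); a species with
#' zero coverage is an error.
#'
#' @param profiles a [chromatogram_set()].
#' @param W a [build_likelihood()] or [compound_target_scores()] matrix
#'   (compound x target).
#' @param weighting label recorded on the output; inferred from the class
#'   of `W` when missing.
#' @return A `species_target_profile` matrix (species x target) with
#'   `coverage` and `weighting` attributes.
#' @export
predict_profile <- function(profiles, W,
                            weighting = c("auto", "binary_likelihood",
                                          "continuous_score")) {
  weighting <- match.arg(weighting)
  if (weighting == "auto")
    weighting <- if (inherits(W, "likelihood_matrix")) "binary_likelihood"
                 else "continuous_score"
  stopifnot(inherits(profiles, "chromatogram_set"))
  W <- unclass(W)
  species <- unique(profiles$species)
  targets <- colnames(W)
  matched <- profiles$compound_id %in% rownames(W)
  if (!all(matched))
    eo_warn(sprintf("%d chromatogram entr(ies) not in the compound matrix; excluded from coverage",
                    sum(!matched)), "coverage_warning")
  out <- matrix(0, length(species), length(targets),
                dimnames = list(species, targets))
  coverage <- stats::setNames(numeric(length(species)), species)
  for (s in species) {
    rows <- profiles$species == s & matched
    coverage[s] <- sum(profiles$fraction[rows])
    if (coverage[s] == 0)
      eo_stop(sprintf("species %s has zero matched chromatogram coverage", s),
              "no_prediction")
    out[s, ] <- colSums(profiles$fraction[rows] *
                          W[profiles$compound_id[rows], , drop = FALSE])
  }
  structure(out, coverage = coverage, weighting = weighting,
            class = c("species_target_profile", class(out)))
}

#' Rank targets per species by predicted action
#'
#' @param profile a [predict_profile()] matrix.
#' @return named list (one per species) of target ids sorted by descending
#'   predicted value, ties by target id.
#' @export
rank_targets <- function(profile) {
  stopifnot(inherits(profile, "species_target_profile"))
  P <- unclass(profile)
  lapply(stats::setNames(rownames(P), rownames(P)), function(s) {
    v <- P[s, ]
    names(v)[order(-v, names(v))]
  })
}

#' Write a species-by-target profile with its coverage report
#'
#' @param profile a [predict_profile()] result.
#' @param csv_path matrix CSV output path.
#' @param json_path JSON report (coverage, weighting) output path; skipped
#'   when NULL.
#' @export
write_profile <- function(profile, csv_path, json_path = NULL) {
  write_matrix_csv(unclass(profile), csv_path, rowname_header = "species")
  if (!is.null(json_path))
    jsonlite::write_json(
      list(weighting = attr(profile, "weighting"),
           coverage = as.list(attr(profile, "coverage"))),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
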