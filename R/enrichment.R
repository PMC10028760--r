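#' Active/decoy benchmark sets
#'
#' Labels used to validate scoring functions: known true ligands (actives,
#' e.g. compounds with reported IC50/EC50/Ki/Kd) versus decoys.
#'
#' @param target_id target the benchmark belongs to.
#' @param labels named character vector, values `"active"` or `"decoy"`,
#'   names ligand ids.
#' @return A `benchmark_set`.
#' @export
benchmark_set <- function(target_id, labels) {
  if (!all(labels %in% c("active", "decoy")))
    eo_stop("labels must be 'active' or 'decoy'", "validation_error")
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    eo_stop("labels must be uniquely named by ligand id", "validation_error")
  if (!any(labels == "active") || !any(labels == "decoy"))
    eo_stop("benchmark needs at least one active and one decoy",
            "validation_error")
  structure(list(target_id = as.character(target_id), labels = labels),
            class = "benchmark_set")
}

#' Read benchmark labels from CSV
#'
#' Columns `ligand_id`, `target_id`, `label`.
#'
#' @param path file path.
#' @return Named list of [benchmark_set()] per target.
#' @export
read_benchmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand_id", "target_id", "label")
  if (!all(need %in% names(df)))
    eo_stop("benchmark file needs columns ligand_id, target_id, label",
            "format_error")
  sets <- lapply(split(df, df$target_id), function(d)
    benchmark_set(d$target_id[1L], stats::setNames(d$label, d$ligand_id)))
  sets
}

#' ROC curve and AUC for an actives-vs-decoys score ranking
#'
#' The AUC equals the Mann-Whitney probability that a randomly chosen active
#' outranks a randomly chosen decoy, ties counted 1/2; it is computed from
#' midranks, which is exact under that convention.
#'
#' @param scores named numeric vector of scores (names = ligand ids),
#'   covering every labelled ligand.
#' @param labels a [benchmark_set()].
#' @param orientation `"lower_is_better"` or `"higher_is_better"`.
#' @return list with `auc` and `roc` (data.frame fpr, tpr along the ranking).
#' @export
roc_auc <- function(scores, labels,
                    orientation = c("lower_is_better", "higher_is_better")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(labels, "benchmark_set"))
  lab <- labels$labels
  miss <- setdiff(names(lab), names(scores))
  if (length(miss))
    eo_stop(sprintf("no score for labelled ligand(s): %s",
                    paste(utils::head(miss, 5L), collapse = ", ")),
            "validation_error")
  g <- goodness(scores[names(lab)], orientation)
  act <- lab == "active"
  n_a <- sum(act); n_d <- sum(!act)
  if (length(unique(g)) == 1L) {
    eo_warn("all scores identical: degenerate ranking, AUC 0.5",
            "degenerate_ranking_warning")
    auc <- 0.5
  } else {
    r <- rank(g, ties.method = "average")
    auc <- (sum(r[act]) - n_a * (n_a + 1) / 2) / (n_a * n_d)
  }
  ord <- order(-g, names(lab))
  tpr <- cumsum(act[ord]) / n_a
  fpr <- cumsum(!act[ord]) / n_d
  list(auc = auc,
       roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Enrichment-factor curve of a ranked ligand list
#'
#' For a screened fraction x, `EF(x)` is the active rate among the top
#' `ceiling(x * N)` ligands divided by the active rate in the whole list:
#' `EF(x) = (actives in top n / n) / (total actives / N)`. `ef_max` is the
#' curve maximum and `ef_max_fraction` the smallest fraction attaining it.
#'
#' @param ranking ligand ids ordered best first (deterministic: sort scores
#'   by goodness, ties by ligand id, before calling).
#' @param labels a [benchmark_set()] covering the ranking.
#' @param fractions screened fractions in (0, 1\], ascending.
#' @param function_id,mode optional provenance labels carried through to the
#'   result.
#' @return An `enrichment_result`: list with `ef_curve` (data.frame
#'   fraction, n_top, ef), `ef_max`, `ef_max_fraction`, plus `auc`,
#'   `function_id`, `mode` when supplied.
#' @export
ef_curve <- function(ranking, labels, fractions = c(0.005, 0.01, 0.02, 0.05,
                                                    0.1, 0.2, 0.5, 1),
                     function_id = NA_character_, mode = NA_character_) {
  stopifnot(inherits(labels, "benchmark_set"))
  if (!length(ranking)) eo_stop("empty ranking", "empty_input")
  if (any(fractions <= 0 | fractions > 1) || is.unsorted(fractions))
    eo_stop("fractions must be ascending values in (0, 1]", "validation_error")
  lab <- labels$labels[ranking]
  if (anyNA(lab))
    eo_stop("ranking contains unlabelled ligands", "validation_error")
  N <- length(ranking)
  n_act <- sum(lab == "active")
  base_rate <- n_act / N
  is_act <- cumsum(lab == "active")
  n_top <- pmin(ceiling(fractions * N), N)
  ef <- (is_act[n_top] / n_top) / base_rate
  ef_max <- max(ef)
  structure(list(function_id = function_id, mode = mode, auc = NA_real_,
                 ef_curve = data.frame(fraction = fractions, n_top = n_top,
                                       ef = ef),
                 ef_max = ef_max,
                 ef_max_fraction = fractions[which(ef == ef_max)[1L]]),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result %s/%s: AUC %.3f, EFmax %.2f at %.1f%% screened>\n",
              x$function_id, x$mode, x$auc, x$ef_max, 100 * x$ef_max_fraction))
  invisible(x)
}

#' Evaluate one scoring function against a benchmark
#'
#' Convenience wrapper: ranks the scored ligands deterministically (by
#' goodness, ties by ligand id), then computes ROC AUC and the EF curve.
#'
#' @inheritParams roc_auc
#' @inheritParams ef_curve
#' @return An `enrichment_result` with `auc` filled in.
#' @export
evaluate_function <- function(scores, labels, orientation,
                              fractions = c(0.005, 0.01, 0.02, 0.05, 0.1,
                                            0.2, 0.5, 1),
                              function_id = NA_character_,
                              mode = NA_character_) {
  scores <- scores[names(scores) %in% names(labels$labels)]
  g <- goodness(scores, orientation)
  ranking <- names(scores)[order(-g, names(scores))]
  res <- ef_curve(ranking, labels, fractions, function_id, mode)
  res$auc <- roc_auc(scores, labels, orientation)$auc
  res
}

#' Select scoring functions by the AUC / early-EFmax rule
#'
#' A (function, mode) pair is kept when its AUC is at least `auc_min` and
#' its EF maximum is first attained no later than `efmax_fraction_max` of
#' the screened database. When both aggregation modes pass for a function,
#' the mode with the better AUC is kept. `force_include` overrides the rule
#' for named functions (useful when a function is known to enrich early
#' despite a sub-0.5 AUC).
#'
#' @param results list of `enrichment_result` for one target.
#' @param auc_min minimum acceptable AUC (default 0.5).
#' @param efmax_fraction_max latest acceptable screened fraction for the EF
#'   maximum (default 0.05, i.e. 5% of the base).
#' @param force_include character vector of function_ids always kept (best
#'   mode by AUC).
#' @return data.frame (function_id, mode, auc, ef_max, ef_max_fraction,
#'   selected); a hard warning is raised when nothing passes.
#' @export
select_functions <- function(results, auc_min = 0.5,
                             efmax_fraction_max = 0.05,
                             force_include = character()) {
  if (!length(results)) eo_stop("no enrichment results given", "empty_input")
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(function_id = r$function_id, mode = r$mode, auc = r$auc,
               ef_max = r$ef_max, ef_max_fraction = r$ef_max_fraction,
               stringsAsFactors = FALSE)))
  tab$passes <- tab$auc >= auc_min & tab$ef_max_fraction <= efmax_fraction_max
  tab$forced <- tab$function_id %in% force_include
  tab$selected <- FALSE
  for (f in unique(tab$function_id)) {
    i <- which(tab$function_id == f & (tab$passes | tab$forced))
    if (length(i))
      tab$selected[i[which.max(tab$auc[i])]] <- TRUE
  }
  if (!any(tab$selected))
    eo_warn("no scoring function passes the AUC/EFmax selection rule",
            "no_function_selected_warning")
  cols <- c("function_id", "mode", "auc", "ef_max", "ef_max_fraction",
            "passes", "forced", "selected")
  out <- tab[order(tab$function_id, tab$mode), cols]
  rownames(out) <- NULL
  out
}
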