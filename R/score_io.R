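#' Docking score tables
#'
#' Long-form docking scores keyed by (ligand, target, model, function,
#' pose rank). Each scoring function carries an orientation —
#' `lower_is_better` for Vina-like energies, `higher_is_better` for
#' probability-like scores — and every comparison in the package is routed
#' through it.
#'
#' @param records data.frame with columns `ligand_id`, `target_id`,
#'   `model_id`, `function_id`, `pose_rank`, `score`.
#' @param orientations named character vector mapping each `function_id` to
#'   `"lower_is_better"` or `"higher_is_better"`.
#' @return A `score_table`: the validated data.frame with an `orientations`
#'   attribute.
#' @export
score_table <- function(records, orientations) {
  need <- c("ligand_id", "target_id", "model_id", "function_id",
            "pose_rank", "score")
  miss <- setdiff(need, names(records))
  if (length(miss))
    eo_stop(sprintf("score table missing column(s): %s",
                    paste(miss, collapse = ", ")), "format_error")
  records <- records[need]
  for (col in c("ligand_id", "target_id", "model_id", "function_id"))
    records[[col]] <- as.character(records[[col]])
  records$pose_rank <- as.integer(records$pose_rank)
  records$score <- as.numeric(records$score)
  if (any(records$pose_rank < 1L, na.rm = TRUE))
    eo_stop("pose_rank must be a positive integer", "validation_error")
  key <- do.call(paste, c(records[c("ligand_id", "target_id", "model_id",
                                    "function_id", "pose_rank")], sep = "\r"))
  if (anyDuplicated(key))
    eo_stop("duplicate (ligand, target, model, function, pose) record",
            "duplicate_record")
  funs <- unique(records$function_id)
  miss <- setdiff(funs, names(orientations))
  if (length(miss))
    eo_stop(sprintf("no orientation declared for function(s): %s",
                    paste(miss, collapse = ", ")), "format_error")
  bad <- !orientations %in% c("lower_is_better", "higher_is_better")
  if (any(bad))
    eo_stop("orientations must be lower_is_better or higher_is_better",
            "validation_error")
  structure(records, orientations = orientations[funs], class =
              c("score_table", "data.frame"))
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table: %d records, %d ligands, %d targets, %d functions, %d models>\n",
              nrow(x), length(unique(x$ligand_id)), length(unique(x$target_id)),
              length(unique(x$function_id)), length(unique(x$model_id))))
  invisible(x)
}

orientations_of <- function(x) attr(x, "orientations")

# signed goodness: larger is always better; orientation recycles over scores
goodness <- function(score, orientation) {
  sgn <- ifelse(orientation == "lower_is_better", -1, 1)
  sgn * score
}

#' Read a docking score table from delimited text
#'
#' CSV/TSV with a header naming the six required columns. Rows whose score
#' does not parse as a number are skipped with a warning reporting their line
#' numbers.
#'
#' @param path file path.
#' @param orientations named orientation vector, or path to a two-column
#'   `key=value` config file (function_id, orientation).
#' @param sep field separator; guessed from the header line when `NULL`.
#' @return A [score_table()].
#' @export
read_score_table <- function(path, orientations, sep = NULL) {
  if (is.character(orientations) && length(orientations) == 1L &&
      file.exists(orientations))
    orientations <- read_orientations(orientations)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "#")
  score_num <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score_num) & !is.na(df$score) | is.na(df$score))
  if (length(bad)) {
    eo_warn(sprintf("skipping %d row(s) with unparseable score (line %s)",
                    length(bad), paste(bad + 1L, collapse = ", ")),
            "parse_warning")
    df <- df[-bad, , drop = FALSE]
    score_num <- score_num[-bad]
  }
  df$score <- score_num
  score_table(df, orientations)
}

#' @rdname read_score_table
#' @export
read_orientations <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2L))
    eo_stop("orientation config lines must be 'function_id=orientation'",
            "format_error")
  stats::setNames(vapply(kv, `[[`, character(1), 2L),
                  vapply(kv, `[[`, character(1), 1L))
}

#' Aggregate docking scores across poses and models
#'
#' The multi-model design is treated like a randomized complete block
#' design: each homology model is a block, each ligand a treatment, each
#' docked pose a repetition. Per (ligand, target, function): within each
#' model take the best pose score (`mode = "best"`) or the mean of the three
#' best poses (`"top3_mean"`, fewer when fewer exist), "best" per the
#' function's orientation; then average across models. Ligands missing from
#' some models are averaged over the models that do have them, with a
#' warning.
#'
#' @param table a [score_table()].
#' @param mode `"best"` or `"top3_mean"`.
#' @return An `aggregated_scores` data.frame (ligand_id, target_id,
#'   function_id, score, n_models) with `mode` and `orientations` attributes.
#' @export
aggregate_scores <- function(table, mode = c("best", "top3_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "score_table"))
  if (!nrow(table)) eo_stop("empty score table", "empty_input")
  ors <- orientations_of(table)
  df <- as.data.frame(table)
  df$g <- goodness(df$score, ors[df$function_id])
  # per (ligand, target, function, model): summarise poses
  per_model <- stats::aggregate(
    g ~ ligand_id + target_id + function_id + model_id, data = df,
    FUN = function(g) {
      g <- sort(g, decreasing = TRUE)
      if (mode == "best") g[1L] else mean(g[seq_len(min(3L, length(g)))])
    })
  agg <- stats::aggregate(g ~ ligand_id + target_id + function_id,
                          data = per_model,
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(agg[c("ligand_id", "target_id", "function_id")],
                    score_g = agg$g[, 1L], n_models = as.integer(agg$g[, 2L]))
  n_models_total <- length(unique(df$model_id))
  if (any(out$n_models < n_models_total))
    eo_warn(sprintf(
      "%d (ligand, target, function) cell(s) missing from some models; averaged over available blocks",
      sum(out$n_models < n_models_total)), "unbalanced_block_warning")
  # report on the original score scale
  out$score <- ifelse(ors[out$function_id] == "lower_is_better",
                      -out$score_g, out$score_g)
  out$score_g <- NULL
  structure(out, mode = mode, orientations = ors,
            class = c("aggregated_scores", "data.frame"))
}

# matrix of goodness values, ligand x function, for one target
goodness_matrix <- function(agg, target_id, function_ids) {
  ors <- orientations_of(agg)
  sub <- agg[agg$target_id == target_id & agg$function_id %in% function_ids, ,
             drop = FALSE]
  missing_fun <- setdiff(function_ids, sub$function_id)
  if (length(missing_fun))
    eo_stop(sprintf("function(s) absent for target %s: %s", target_id,
                    paste(missing_fun, collapse = ", ")), "missing_function")
  ligands <- sort(unique(sub$ligand_id))
  G <- matrix(NA_real_, length(ligands), length(function_ids),
              dimnames = list(ligands, function_ids))
  G[cbind(match(sub$ligand_id, ligands), match(sub$function_id, function_ids))] <-
    goodness(sub$score, ors[sub$function_id])
  G
}

#' Rank ligands by average rank over scoring functions
#'
#' Per function, rank 1 is the best score under that function's orientation;
#' ties share the mean of the occupied ranks. Ligands are ordered by the
#' mean rank across the requested functions, ties broken by ligand id.
#'
#' @param agg an [aggregate_scores()] result.
#' @param target_id target to rank within.
#' @param function_ids scoring functions to average over (all present for
#'   the target by default).
#' @return data.frame (ligand_id, mean_rank, per-function rank columns)
#'   ordered best first.
#' @export
rank_ligands <- function(agg, target_id, function_ids = NULL) {
  stopifnot(inherits(agg, "aggregated_scores"))
  if (is.null(function_ids))
    function_ids <- sort(unique(agg$function_id[agg$target_id == target_id]))
  G <- goodness_matrix(agg, target_id, function_ids)
  R <- apply(-G, 2L, rank, ties.method = "average", na.last = "keep")
  if (is.null(dim(R))) R <- matrix(R, ncol = length(function_ids),
                                   dimnames = list(rownames(G), function_ids))
  mean_rank <- rowMeans(R, na.rm = TRUE)
  ord <- order(mean_rank, rownames(G))
  out <- data.frame(ligand_id = rownames(G)[ord], mean_rank = mean_rank[ord],
                    R[ord, , drop = FALSE], row.names = NULL,
                    check.names = FALSE)
  out
}

#' @rdname read_score_table
#' @param x a `score_table` to write.
#' @export
write_score_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
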