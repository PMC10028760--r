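# shared fixtures, built in code

fp <- function(bits, scheme = "test") fingerprint(bits, scheme)

# library of n ligands with explicit fingerprints and fixture keys
# (canonical/flat keys are plain strings so no toolkit is involved)
fixture_library <- function(bit_rows, ids = sprintf("L%02d", seq_along(bit_rows)),
                            flat_keys = NULL, canonical_keys = NULL) {
  fps <- lapply(bit_rows, fp)
  names(fps) <- ids
  ligand_library(ids, smiles = ids, fingerprints = fps,
                 canonical_keys = canonical_keys %||% ids,
                 flat_keys = flat_keys %||% ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_fingerprints <- function(n, n_bits = 64, p = 0.4) {
  lapply(seq_len(n), function(i) fp(runif(n_bits) < p))
}

# brute-force Tanimoto popcount oracle
tanimoto_oracle <- function(a, b) {
  inter <- sum(a$bits & b$bits)
  uni <- sum(a$bits | b$bits)
  if (uni == 0) 1 else inter / uni
}

# brute-force AUC by pairwise comparison (ties 0.5)
auc_oracle <- function(goodness, is_active) {
  a <- goodness[is_active]; d <- goodness[!is_active]
  cmp <- outer(a, d, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# two-block distance matrix fixture: within <= w, between >= b
block_distmat <- function(sizes, within = 0.1, between = 0.9,
                          jitter = 0.05, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    base <- if (lab[i] == lab[j]) within else between
    d[i, j] <- d[j, i] <- base + runif(1, -jitter, jitter)
  }
  dimnames(d) <- list(sprintf("L%02d", 1:n), sprintf("L%02d", 1:n))
  attr(d, "blocks") <- lab
  d
}

# a small aggregated-scores object from a plain score data.frame
quick_scores <- function(df, orientations, mode = "best") {
  aggregate_scores(score_table(df, orientations), mode)
}

score_rows <- function(ligand_id, target_id = "T1", model_id = "M1",
                       function_id = "F1", pose_rank = 1, score) {
  data.frame(ligand_id = ligand_id, target_id = target_id,
             model_id = model_id, function_id = function_id,
             pose_rank = pose_rank, score = score,
             stringsAsFactors = FALSE)
}
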