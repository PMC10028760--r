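#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can dispatch on failure kind.
eo_stop <- function(msg, class, call. = FALSE, data = NULL) {
  cond <- errorCondition(msg, class = c(class, "eoscreen_error"), data = data)
  stop(cond)
}

eo_warn <- function(msg, class = "eoscreen_warning") {
  warning(warningCondition(msg, class = c(class, "eoscreen_warning")))
}

# sd with selectable denominator; ddof = 1 reproduces stats::sd
sd_ddof <- function(x, ddof = 1) {
  n <- sum(!is.na(x))
  if (n - ddof <= 0) return(NA_real_)
  sqrt(sum((x - mean(x, na.rm = TRUE))^2, na.rm = TRUE) / (n - ddof))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic RNG scope: runs expr under set.seed(seed), restores state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    eo_stop(sprintf("'%s' must be a single finite number", name), "validation_error")
}
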