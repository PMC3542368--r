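# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  x
}

# Validate a patients x genes binary incidence matrix.
check_mutation_matrix <- function(x) {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x))) {
    stop("mutation matrix must be a matrix with patient rownames and gene colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop("mutation matrix has duplicate patient IDs or gene symbols", call. = FALSE)
  }
  if (!all(x %in% c(0L, 1L))) {
    stop("mutation matrix entries must be 0 or 1", call. = FALSE)
  }
  invisible(x)
}
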