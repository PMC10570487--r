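#' Derive a reproducible child seed
#'
#' Folds a root seed and any number of integer components into a single
#' seed below 2^31, so that parallel or per-unit random streams (for
#' example one per channel pair in the bootstrap null) are reproducible
#' from one root seed.
#'
#' @param root Integer root seed.
#' @param ... Further integer components (band index, pair index, ...).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.numeric(root) %% m
  for (x in c(...)) {
    s <- (s * 69069 + as.numeric(x) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number")
}
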