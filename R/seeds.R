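#' Derive a child seed from a master seed and integer coordinates
#'
#' Counter-based seed derivation: every (experiment, cell, iteration)
#' coordinate maps to a fixed child seed regardless of execution order, so
#' cells can be computed in any order (or in parallel) with identical results.
#' A small multiply-xor mixer keeps results in the positive 32-bit range
#' required by [set.seed()].
#'
#' @param master integer master seed.
#' @param ... further integer coordinates (experiment index, cell index,
#'   iteration index, ...).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1, 3)
derive_seed <- function(master, ...) {
  idx <- c(master, ...)
  stopifnot(length(idx) >= 1, all(is.finite(idx)))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (v in as.numeric(idx)) {
    # multipliers kept < 2^22 so h * mult stays exact in double precision
    h <- (h + (v %% m) + 1) %% m
    h <- (h * 48271) %% m    # Lehmer minimal-standard step
    h <- (h * 69621) %% m    # second step for diffusion across coordinates
  }
  as.integer(h %% 2147483646 + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
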