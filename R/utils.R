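# Internal helpers shared across the pipeline.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded pipeline stages do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic sub-seed from a master seed
#'
#' Independent pipeline stages draw their own sub-seed so that the same
#' master seed reproduces the whole run bit-for-bit while stages stay
#' decoupled. A Lehmer-style step keeps the result a valid 32-bit seed.
#'
#' @param master integer master seed.
#' @param k stage index (>= 1).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(master, k) {
  m <- 2147483647
  x <- (abs(as.double(master)) %% m)
  for (i in seq_len(k)) x <- (x * 48271 + 11) %% m
  as.integer(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# z-score columns; errors on constant columns (which break both the BIC
# score and the skewness statistics).
standardize_columns <- function(x, what = "column") {
  x <- as.matrix(x)
  s <- apply(x, 2, sd)
  if (any(!is.finite(x))) stopf("non-finite values in input matrix")
  if (any(s == 0)) {
    stopf("constant %s(s): %s", what,
          paste(which(s == 0), collapse = ", "))
  }
  scale(x, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

node_names <- function(p, nodes = NULL) {
  if (is.null(nodes)) sprintf("V%d", seq_len(p)) else as.character(nodes)
}
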