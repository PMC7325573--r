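#' Run an expression under a local RNG seed
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr`, then
#' restores the state, so package internals never disturb the user's random
#' stream.  With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer scalar or `NULL`.
#' @param expr expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
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

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Different named components (plant, tuner, controller, ...) of one
#' experiment must be independently reproducible from a single master seed.
#' The derived seed is a deterministic hash of the master seed and the
#' stream name, kept strictly below 2^31 - 1.
#'
#' @param master_seed integer scalar.
#' @param stream character name of the sub-stream.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "plant") != derive_seed(1, "tuner")
derive_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stream), length(stream) == 1L)
  h <- as.double(master_seed) %% 2147483647
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# shared argument checks -----------------------------------------------------

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name)
  if (x < min || x != as.integer(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
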