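# Internal helpers shared across modules.

#' Evaluate code under a local random seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores (or removes) the
#' global `.Random.seed`, so generator functions are deterministic without
#' leaking state into the caller's session.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with a consistent invalid-argument style
abort_arg <- function(...) stop(sprintf(...), call. = FALSE)

# single non-missing flag
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

`%||%` <- function(a, b) if (is.null(a)) b else a
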