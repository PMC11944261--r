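# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All exported stochastic operations go
# through this so that library code never clobbers the user's RNG stream.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a named substream seed from a root seed
#'
#' All pipeline randomness flows from one root seed through named
#' substreams (simulation, split, base nets, meta-learners, permutation),
#' so each stage is reproducible independently of how many random numbers
#' the other stages consume. The derived seed always stays below 2^31 - 1.
#'
#' @param seed Integer root seed.
#' @param name Substream name (any string).
#' @return An integer seed.
#' @examples
#' substream_seed(1, "simulate")
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vf <- function(...) stop(sprintf(...), call. = FALSE)
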