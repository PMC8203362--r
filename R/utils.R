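#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a master seed and a tag
#'
#' All randomness in the package flows from one user-supplied seed; independent
#' streams (data split, batch sampler, augmentation, weight init, ...) use
#' seeds derived deterministically from it, kept within the 32-bit signed
#' integer range.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the stream.
#' @return an integer seed in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  x <- (as.double(seed) %% 2147483647) + 1
  for (i in 1:3) x <- (x * 48271 + h) %% 2147483647
  as.integer(x %% 2147483645L + 1L)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so library code never perturbs the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
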