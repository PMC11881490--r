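# Self-contained random streams.
#
# Every stochastic entry point in the package takes an explicit seed or a
# stream object, so training, masking, sampling and splitting are reproducible
# without touching the caller's global .Random.seed. A stream is an
# environment holding a saved Mersenne-Twister state; each draw swaps the
# state in, draws, and restores whatever the caller had.

#' Create a reproducible random stream
#'
#' @param seed Integer seed.
#' @return An environment usable with [rng_runif()], [rng_rnorm()],
#'   [rng_sample()].
#' @export
rng_make <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- .Random.seed
  .restore_global_seed(old)
  env
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.with_stream <- function(rng, fn) {
  old <- .save_global_seed()
  assign(".Random.seed", rng$state, envir = globalenv())
  out <- fn()
  rng$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  out
}

#' @rdname rng_make
#' @param rng A stream from [rng_make()].
#' @param n Number of draws.
#' @export
rng_runif <- function(rng, n) .with_stream(rng, function() runif(n))

#' @rdname rng_make
#' @param mean,sd Normal parameters.
#' @export
rng_rnorm <- function(rng, n, mean = 0, sd = 1) {
  .with_stream(rng, function() rnorm(n, mean, sd))
}

#' @rdname rng_make
#' @param x Population size (sampling from `seq_len(x)`).
#' @param size Sample size.
#' @param replace Sample with replacement?
#' @export
rng_sample <- function(rng, x, size, replace = FALSE) {
  .with_stream(rng, function() sample.int(x, size, replace = replace))
}

# Derive a child seed from a stream (for handing to sub-components).
rng_child_seed <- function(rng) {
  as.integer(floor(rng_runif(rng, 1) * 2147483646)) + 1L
}
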