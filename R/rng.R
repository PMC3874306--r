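#' Deterministic named random substreams
#'
#' A single master seed derives independent, named substreams so that each
#' stochastic operator (population initialization, selection, crossover,
#' mutation, data generation) is reproducible in isolation: re-running one
#' operator with its stream does not perturb the draws of any other.
#'
#' Streams are Mersenne-Twister states swapped in and out of R's global RNG
#' around each draw; the global \code{.Random.seed} is always restored, so
#' package code never clobbers a user's RNG state.
#'
#' @param seed integer master (or derived) seed.
#' @return an object of class \code{rng_stream}.
#' @export
rng_stream <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("rng_stream: seed must be an integer")
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed, kind = "Mersenne-Twister")
  e$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Derive a named sub-seed from a master seed
#'
#' Hashes the stream name into the master seed so that distinct names give
#' unrelated substreams. The result is kept inside the 32-bit signed range
#' required by \code{set.seed}.
#'
#' @param master integer master seed.
#' @param name character stream name (e.g. \code{"mutation"}).
#' @return integer sub-seed.
#' @export
derive_seed <- function(master, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  as.integer((as.double(master) %% 2147483647 * 2654435 + h) %% 2147483647)
}

# Run fn() with the stream's RNG state installed; advance the stream.
stream_do <- function(stream, fn) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}
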