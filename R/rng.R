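#' Independent seeded random streams
#'
#' An `rng_stream` snapshots its own copy of R's random-number-generator state.
#' Every chain, replica, and exchange scheduler in the engine owns one, so that
#' draws made by one component can never perturb another: results are identical
#' whether runs execute sequentially or concurrently, and a single master seed
#' reproduces a whole multi-run optimization byte for byte.
#'
#' Draws are made by activating the stream with [with_stream()], which swaps the
#' stream's state into the global RNG, evaluates an expression, and swaps the
#' (advanced) state back out. User callbacks therefore use ordinary `runif()`,
#' `rnorm()`, `sample()` and friends; the engine decides which stream they draw
#' from.
#'
#' @param seed Integer seed initialising the stream (via [set.seed()]).
#' @return An object of class `rng_stream`.
#' @examples
#' r <- rng_stream(42)
#' a <- with_stream(r, runif(3))
#' b <- with_stream(r, runif(3))   # continues the stream, a != b
#' identical(a, with_stream(rng_stream(42), runif(3)))
#' @export
rng_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  e$active <- FALSE
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression using a stream's RNG state
#'
#' Activates `rng`, evaluates `expr`, stores the advanced state back into the
#' stream and restores whatever global RNG state was in place before. Streams
#' must not be nested within themselves (that would silently fork the state);
#' doing so is an error.
#'
#' @param rng An [rng_stream()].
#' @param expr Expression to evaluate; its random draws consume the stream.
#' @return The value of `expr`.
#' @export
with_stream <- function(rng, expr) {
  if (!inherits(rng, "rng_stream")) stop("rng must be an rng_stream", call. = FALSE)
  if (isTRUE(rng$active)) stop("rng_stream is already active (nested use)", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  rng$active <- TRUE
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    rng$active <- FALSE
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
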