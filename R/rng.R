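#' Reproducible random-number streams
#'
#' Streams wrap R's L'Ecuyer-CMRG generator so that every replicate of a
#' simulation, and every animal within a replicate, draws from its own
#' independent substream. Adding animals to a herd therefore never perturbs
#' the trajectories of existing animals, and replicate k is unaffected by
#' how long replicate k-1 ran.
#'
#' A stream is an environment holding the current generator state; all
#' `herdsim` sampling functions accept `rng = NULL` (draw from the session
#' RNG) or a stream created here.
#'
#' @param seed integer root seed.
#' @return an object of class `herd_stream`.
#' @examples
#' s <- rng_stream(42)
#' x <- with_stream(s, runif(3))
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  state <- local({
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_seed(old))
    set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
    get(".Random.seed", globalenv(), inherits = FALSE)
  })
  stream_from_state(state)
}

stream_from_state <- function(state) {
  e <- new.env(parent = emptyenv())
  e$state <- state
  e$origin <- state   # fixed birth state; substreams are derived from this
  e$sub_cache_state <- state
  e$sub_cache_index <- 0L
  class(e) <- "herd_stream"
  e
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Evaluate an expression under a stream's RNG state
#'
#' Swaps the stream state into `.Random.seed`, evaluates `expr`, then saves
#' the advanced state back into the stream and restores the session RNG.
#' With `rng = NULL` the expression simply runs against the session RNG.
#'
#' @param rng a `herd_stream` or NULL.
#' @param expr expression performing random draws.
#' @export
with_stream <- function(rng, expr) {
  if (is.null(rng)) return(expr)
  stopifnot(inherits(rng, "herd_stream"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv(), inherits = FALSE)
    restore_seed(old)
  })
  expr
}

#' Derive the k-th independent stream (used for replicates)
#'
#' @param rng a `herd_stream`.
#' @param k nonnegative integer offset; `k = 0` returns a copy of the origin.
#' @export
next_stream <- function(rng, k = 1L) {
  stopifnot(inherits(rng, "herd_stream"), k >= 0)
  st <- rng$origin
  for (i in seq_len(k)) st <- parallel::nextRNGStream(st)
  stream_from_state(st)
}

#' Derive the substream keyed by an integer id (used for animals)
#'
#' Substream `id` is a pure function of the parent stream's origin and `id`;
#' sequential ids are served from a cache so cost is O(1) amortized.
#'
#' @param rng parent `herd_stream`.
#' @param id positive integer key.
#' @export
substream <- function(rng, id) {
  stopifnot(inherits(rng, "herd_stream"), id >= 1)
  id <- as.integer(id)
  if (id < rng$sub_cache_index) {      # non-sequential lookup: restart walk
    rng$sub_cache_state <- rng$origin
    rng$sub_cache_index <- 0L
  }
  st <- rng$sub_cache_state
  for (i in seq_len(id - rng$sub_cache_index))
    st <- parallel::nextRNGSubStream(st)
  rng$sub_cache_state <- st
  rng$sub_cache_index <- id
  stream_from_state(st)
}
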