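# Reproducible per-agent random streams built on L'Ecuyer-CMRG substreams
# (parallel::nextRNGStream). A stream is an environment holding a
# .Random.seed state; draws swap it into the session RNG and store the
# advanced state back, so streams are independent of each other and of the
# session RNG between draws.

new_stream <- function(seed_state) {
  e <- new.env(parent = emptyenv())
  e$state <- seed_state
  class(e) <- "forage_stream"
  e
}

#' Create the master random stream for a run
#'
#' @param master_seed Integer master seed.
#' @return A `forage_stream` object.
#' @export
rng_stream <- function(master_seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_session_seed(old))
  suppressWarnings(set.seed(as.integer(master_seed), kind = "L'Ecuyer-CMRG"))
  new_stream(get(".Random.seed", globalenv()))
}

restore_session_seed <- function(old) {
  # when no session seed existed beforehand, the stream's advanced state is
  # simply left in place; repeatedly removing .Random.seed would dominate
  # the cost of small draws
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Derive an independent per-agent random stream
#'
#' Agent `agent_id` receives the `agent_id`-th L'Ecuyer-CMRG substream of
#' the master seed; substream 0 is reserved for the environment (pheromone
#' decay). Streams are reproducible and pairwise independent.
#'
#' @param master_seed Integer master seed shared by the whole run.
#' @param agent_id Non-negative integer; 0 is the environment stream.
#' @return A `forage_stream` object.
#' @export
derive_agent_stream <- function(master_seed, agent_id) {
  stopifnot(agent_id >= 0)
  s <- rng_stream(master_seed)$state
  for (i in seq_len(agent_id)) s <- parallel::nextRNGStream(s)
  new_stream(s)
}

# n uniforms from a stream (or the session RNG when stream is NULL)
draw_runif <- function(n, stream = NULL) {
  if (is.null(stream)) return(stats::runif(n))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  u <- stats::runif(n)
  stream$state <- get(".Random.seed", globalenv())
  restore_session_seed(old)
  u
}

#' @export
print.forage_stream <- function(x, ...) {
  cat("<forage_stream> L'Ecuyer-CMRG substream\n")
  invisible(x)
}
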