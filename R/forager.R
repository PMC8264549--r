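# One forager: the behavioral controller tying inference to ecology.
# Outbound (unladen) ants follow pheromone preferences only; after touching
# the food scent they become laden, gain a nest-ward bias, and deposit one
# unit of trail pheromone at every cell they move to until the home scent
# clears them and the round trip is counted.

#' Create a forager
#'
#' @param id Integer agent id.
#' @param position Starting `(row, col)` cell (the nest, normally).
#' @param stream The agent's own `forage_stream`.
#' @return An object of class `forager`.
#' @export
new_forager <- function(id, position, stream) {
  structure(list(id = as.integer(id), position = as.integer(position),
                 laden = FALSE, round_trips = 0L, stream = stream),
            class = "forager")
}

#' @export
print.forager <- function(x, ...) {
  cat(sprintf("<forager %d> at (%d,%d), %s, %d round trips\n",
              x$id, x$position[1], x$position[2],
              if (x$laden) "laden" else "unladen", x$round_trips))
  invisible(x)
}

#' Homing bias of a laden forager
#'
#' A laden forager is biased toward the nest entrance: every policy whose
#' destination strictly decreases the Euclidean distance to the nest earns
#' an additive log-space bonus `kappa`; all other policies get 0. Unladen
#' foragers get an all-zero bonus (outbound motion is pheromone-biased
#' only).
#'
#' @param position Current `(row, col)`.
#' @param nest Nest `(row, col)`.
#' @param feasible 9 feasibility flags from [local_window()].
#' @param kappa Bonus weight.
#' @param laden Whether the forager is carrying food.
#' @return Numeric vector of 9 bonuses.
#' @export
homing_bonus <- function(position, nest, feasible, kappa = 3, laden = TRUE) {
  if (!laden || kappa == 0) return(rep(0, N_POLICIES))
  dest_r <- position[1] + DIR_OFFSETS[, 1]
  dest_c <- position[2] + DIR_OFFSETS[, 2]
  d_here <- sqrt(sum((position - nest)^2))
  d_dest <- sqrt((dest_r - nest[1])^2 + (dest_c - nest[2])^2)
  bonus <- ifelse(d_dest < d_here, kappa, 0)
  bonus[!feasible] <- 0
  unname(bonus)
}

#' Simulate a single forager's walk
#'
#' Steps one forager through an arena for `n_steps` cycles of action and
#' inference, recording its position after every step. Intended for
#' single-agent diffusion studies (e.g. the Brownian limit of a
#' flat-preference forager on an open arena); the arena's field is carried
#' along, so a laden walker would deposit as usual.
#'
#' @param arena A `forage_arena`.
#' @param model A `forage_model`.
#' @param n_steps Number of steps.
#' @param stream The walker's `forage_stream`.
#' @param start Starting `(row, col)`; defaults to the arena's nest.
#' @return Integer matrix of `n_steps + 1` rows (`row`, `col`), the first
#'   being the start position.
#' @export
simulate_walk <- function(arena, model, n_steps, stream, start = NULL) {
  if (is.null(start)) start <- arena$nest
  f <- new_forager(1L, start, stream)
  pos <- matrix(0L, n_steps + 1L, 2L,
                dimnames = list(NULL, c("row", "col")))
  pos[1L, ] <- f$position
  for (t in seq_len(n_steps)) {
    out <- step_forager(f, arena, model)
    f <- out$forager
    arena <- out$arena
    pos[t + 1L, ] <- f$position
  }
  pos
}

#' Time-origin-averaged mean squared displacement
#'
#' The standard MSD estimator for a recorded trajectory: for each lag tau,
#' the squared displacement `|x(t0 + tau) - x(t0)|^2` averaged over time
#' origins t0 (thinned by `by` for speed). For an unbiased 9-neighborhood
#' random walk the curve is linear with slope 4/3 cells^2 per step.
#'
#' @param positions Two-column position matrix as from [simulate_walk()].
#' @param lags Integer vector of lags (steps).
#' @param by Origin-thinning stride.
#' @return Tibble with `lag` and `msd`.
#' @export
mean_squared_displacement <- function(positions, lags, by = 10L) {
  n <- nrow(positions)
  stopifnot(max(lags) < n)
  msd <- vapply(lags, function(tau) {
    o <- seq(1L, n - tau, by = by)
    mean((positions[o + tau, 1] - positions[o, 1])^2 +
           (positions[o + tau, 2] - positions[o, 2])^2)
  }, numeric(1))
  tibble::tibble(lag = as.integer(lags), msd = msd)
}

#' Advance one forager by one step of action and inference
#'
#' Executes the per-step cycle: (1) sense the local 3x3 window; (2) re-cut
#' the likelihood A; (3) infer the local state from the center-cell level;
#' (4) score the 9 one-step policies by expected free energy; (5) form the
#' policy posterior, adding the homing bonus if laden; (6) sample (or
#' argmax) an action; (7) move; (8) if laden, deposit pheromone at the new
#' position; (9) evaluate scent triggers - food scent while unladen makes
#' the forager laden, home scent while laden unloads it and counts one
#' round trip.
#'
#' @param forager A `forager`.
#' @param arena A `forage_arena` whose `time` field holds the current step.
#' @param model A `forage_model`.
#' @return List with the updated `forager` and `arena`.
#' @export
step_forager <- function(forager, arena, model) {
  win <- local_window(arena, forager$position)
  A <- remap_likelihood(win$levels)
  qs <- infer_states(A, model$D, win$levels[1])
  G <- expected_free_energy(A, model$Bstack %||% model$B, model$C, qs)
  bonus <- homing_bonus(forager$position, arena$nest, win$feasible,
                        kappa = model$kappa, laden = forager$laden)
  qpi <- policy_posterior(G, win$feasible, gamma = model$gamma,
                          homing_bonus = bonus)
  a <- sample_action(qpi, forager$stream, mode = model$action_mode)
  forager$position <- forager$position + DIR_OFFSETS[a, ]
  if (forager$laden)
    arena <- deposit_pheromone(arena, forager$position)
  trig <- sense_triggers(arena, forager$position, arena$time)
  if (!forager$laden && trig$food_scent) {
    forager$laden <- TRUE
  } else if (forager$laden && trig$home_scent) {
    forager$laden <- FALSE
    forager$round_trips <- forager$round_trips + 1L
  }
  list(forager = forager, arena = arena)
}
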