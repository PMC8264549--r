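# Colony-level phenotypes: swarm distance coefficient and round-trip
# performance. Arm pheromone mass lives with the arena (arm_pheromone_mass).

#' Swarm distance coefficient
#'
#' The swarm-coherence metric: Euclidean distances between cell centers of
#' every ordered pair of ants, summed and divided by the number of ants N
#' (`mode = "sum_over_n"`, the default), so for a fixed spatial spread the
#' metric scales with N - 1. `mode = "mean_pairwise"` instead averages over
#' the N(N-1) ordered pairs, giving the mean inter-ant distance.
#'
#' @param positions Ant positions: a 2-column matrix or a data frame with
#'   `row` and `col` columns, one row per ant.
#' @param mode `"sum_over_n"` or `"mean_pairwise"`.
#' @return A single non-negative number; 0 when all ants share one cell.
#' @examples
#' distance_coefficient(rbind(c(0, 0), c(3, 4)))  # (5 + 5) / 2 = 5
#' @export
distance_coefficient <- function(positions,
                                 mode = c("sum_over_n", "mean_pairwise")) {
  mode <- match.arg(mode)
  if (is.data.frame(positions))
    positions <- cbind(positions$row, positions$col)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(n) || n < 1L)
    stop("`positions` must contain at least one ant", call. = FALSE)
  if (n == 1L) return(0)
  total <- 2 * sum(stats::dist(positions))  # ordered pairs
  if (mode == "sum_over_n") total / n else total / (n * (n - 1))
}

#' Cumulative round-trip time series
#'
#' Colony-wide cumulative round trips (summed over all foragers) at each
#' step of a run; equals the `cumulative_round_trips` metric column and is
#' re-derived here from the per-agent trajectory records.
#'
#' @param result A `forage_sim`.
#' @return Tibble with `step` and `round_trips`.
#' @export
round_trips_timeseries <- function(result) {
  stopifnot(inherits(result, "forage_sim"))
  result$trajectories |>
    dplyr::summarise(round_trips = sum(.data$round_trips),
                     .by = "step") |>
    dplyr::arrange(.data$step)
}

#' Plateau distance coefficient
#'
#' Time-average of the distance coefficient over the post-convergence
#' window (steps 500 to the end by default, where colonies have settled
#' onto their characteristic coherence range).
#'
#' @param result A `forage_sim`.
#' @param from First step (0-based) included in the average.
#' @return A single number.
#' @export
plateau_distance_coefficient <- function(result, from = 500L) {
  stopifnot(inherits(result, "forage_sim"))
  m <- dplyr::filter(result$metrics, .data$step >= from)
  if (!nrow(m)) m <- result$metrics
  mean(m$distance_coefficient)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' Returns the per-agent trajectory table: one row per (step, ant) with
#' position, ladenness and cumulative round trips.
#'
#' @param x A `forage_sim`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy forage_sim
#' @export
tidy.forage_sim <- function(x, ...) x$trajectories

#' One-row summary of a simulation
#'
#' @param x A `forage_sim`.
#' @param ... Unused.
#' @return Tibble with colony size, steps, preference kind, total round
#'   trips, plateau distance coefficient and final per-arm pheromone mass.
#' @export
glance.forage_sim <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), , drop = FALSE]
  tibble::tibble(
    n_ants = x$config$n_ants,
    n_steps = x$config$n_steps,
    preference = x$config$preference,
    master_seed = x$config$master_seed,
    total_round_trips = if (nrow(last)) last$cumulative_round_trips else 0L,
    plateau_dc = plateau_distance_coefficient(x),
    final_left_mass = if (nrow(last)) last$left_arm_mass else 0,
    final_right_mass = if (nrow(last)) last$right_arm_mass else 0)
}
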