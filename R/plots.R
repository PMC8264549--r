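# ggplot2 views of a run: metric traces and pheromone-field maps.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the colony-level metric traces of a run
#'
#' Distance coefficient, cumulative round trips and per-arm pheromone mass
#' against time, with food-switch steps marked.
#'
#' @param sim A `forage_sim`.
#' @return A ggplot.
#' @export
plot_metrics <- function(sim) {
  stopifnot(inherits(sim, "forage_sim"))
  long <- sim$metrics |>
    dplyr::select(!"food_arm") |>
    tidyr::pivot_longer(!"step", names_to = "metric")
  last_step <- max(sim$metrics$step)
  switches <- if (last_step >= sim$config$switch_period)
    seq(sim$config$switch_period, last_step, by = sim$config$switch_period)
  else numeric(0)
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_vline(xintercept = switches, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "step", y = NULL,
                  title = sprintf("%d ants, %s preferences",
                                  sim$config$n_ants, sim$config$preference)) +
    ggplot2::theme_minimal()
}

#' Map the pheromone field with ants overlaid
#'
#' @param sim A `forage_sim`.
#' @param step Snapshot step to draw (defaults to the last snapshot; the
#'   final field is used when no snapshots were recorded).
#' @return A ggplot.
#' @export
plot_field <- function(sim, step = NULL) {
  stopifnot(inherits(sim, "forage_sim"))
  if (is.null(step)) {
    field <- if (length(sim$snapshots))
      sim$snapshots[[length(sim$snapshots)]] else sim$final_field
    step <- if (length(sim$snapshots))
      as.integer(utils::tail(names(sim$snapshots), 1))
    else max(sim$metrics$step)
  } else {
    field <- sim$snapshots[[as.character(step)]]
    if (is.null(field)) stop("no snapshot at step ", step, call. = FALSE)
  }
  df <- tibble::tibble(
    row = as.vector(row(field)), col = as.vector(col(field)),
    level = as.vector(field), walkable = as.vector(sim$walkable))
  ants <- dplyr::filter(sim$trajectories, .data$step == !!step)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(
      fill = ifelse(.data$walkable, .data$level, NA_integer_))) +
    ggplot2::geom_point(data = ants, size = 0.8, colour = "#2166ac") +
    ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "grey20",
                                  limits = c(1, 10), name = "pheromone") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = sprintf("step %d", step)) +
    ggplot2::theme_minimal()
}

#' @method autoplot forage_sim
#' @export
autoplot.forage_sim <- function(object, what = c("metrics", "field"), ...) {
  what <- match.arg(what)
  if (what == "metrics") plot_metrics(object) else plot_field(object, ...)
}
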