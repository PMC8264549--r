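# Configuration files, run outputs and the animated rendering of the
# pheromone field. Configs are YAML key-value files mirroring sim_config()
# field for field; tables are CSV; fields are delimited-text integer
# grids; the animation is a multi-frame raster (TIFF).

#' Load a simulation configuration from a YAML file
#'
#' Missing keys take the [sim_config()] defaults; unknown keys and
#' out-of-range values raise a configuration error naming the key. An
#' empty file yields the full default configuration.
#'
#' @param path Path to a YAML config file.
#' @return A `forage_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

#' Write a configuration to a YAML file
#'
#' @param config A `forage_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "forage_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write the full output bundle of a run
#'
#' Emits, under `dir`: `manifest.json` (resolved config, package version,
#' seed, file inventory, wall-clock stamp), `metrics.csv`,
#' `trajectories.csv`, `final_field.txt` and `walkable.txt` (delimited
#' integer grids), and one `field_<step>.txt` grid per snapshot. Everything
#' parses back cleanly with the matching readers.
#'
#' @param sim A `forage_sim`.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_run_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "forage_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(sim$trajectories, file.path(dir, "trajectories.csv"))
  write_field_grid(sim$final_field, file.path(dir, "final_field.txt"))
  write_field_grid(sim$walkable * 1L, file.path(dir, "walkable.txt"))
  snap_files <- character(0)
  for (s in names(sim$snapshots)) {
    f <- sprintf("field_%05d.txt", as.integer(s))
    write_field_grid(sim$snapshots[[s]], file.path(dir, f))
    snap_files <- c(snap_files, f)
  }
  manifest <- list(
    package = "stigmergy",
    version = as.character(utils::packageVersion("stigmergy")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    master_seed = sim$config$master_seed,
    config = unclass(sim$config)[!vapply(unclass(sim$config), is.null,
                                         logical(1))],
    files = c("metrics.csv", "trajectories.csv", "final_field.txt",
              "walkable.txt", snap_files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# one RGB frame: pheromone in white-to-orange on walkable cells, walls
# dark, ants drawn as blue pixels
frame_rgb <- function(field, walkable, ants = NULL) {
  h <- nrow(field); w <- ncol(field)
  x <- (field - 1) / (N_LEVELS - 1)
  r <- ifelse(walkable, 1, 0.12)
  g <- ifelse(walkable, 1 - 0.55 * x, 0.12)
  b <- ifelse(walkable, 1 - x, 0.12)
  if (!is.null(ants) && nrow(ants)) {
    ij <- cbind(ants[, 1], ants[, 2])
    r[ij] <- 0.1; g[ij] <- 0.2; b[ij] <- 0.9
  }
  array(c(r, g, b), dim = c(h, w, 3))
}

#' Render an animation of a run
#'
#' Writes a multi-frame raster (TIFF) of the pheromone field with ant
#' positions overlaid, one frame per recorded snapshot. Frames can be
#' decoded with `tiff::readTIFF(path, all = TRUE)`.
#'
#' @param sim A `forage_sim` with at least one snapshot.
#' @param path Output file path (`.tiff`).
#' @param scale Integer pixel-multiplication factor per cell.
#' @return `path`, invisibly.
#' @export
render_animation <- function(sim, path, scale = 4L) {
  stopifnot(inherits(sim, "forage_sim"))
  if (!length(sim$snapshots))
    stop("no snapshots recorded; set `snapshot_every` > 0", call. = FALSE)
  frames <- lapply(names(sim$snapshots), function(s) {
    t0 <- as.integer(s)
    ants <- dplyr::filter(sim$trajectories, .data$step == t0)
    fr <- frame_rgb(sim$snapshots[[s]], sim$walkable,
                    as.matrix(ants[, c("row", "col")]))
    if (scale > 1L)
      fr <- fr[rep(seq_len(nrow(fr)), each = scale),
               rep(seq_len(ncol(fr)), each = scale), , drop = FALSE]
    fr
  })
  ok <- tiff::writeTIFF(frames, path)
  if (!isTRUE(all(ok)) && !identical(ok, length(frames)))
    stop("failed to write animation to ", path, call. = FALSE)
  invisible(path)
}
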