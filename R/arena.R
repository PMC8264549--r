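# T-maze arena: geometry, pheromone field, reallocation matrix, food
# schedule, deposition and decay. The arena doubles as the generative
# process from which each forager's local likelihood is re-cut every step.

# Canonical 9-neighborhood order shared by window cells, hidden states and
# policies: [stay, N, NE, E, SE, S, SW, W, NW]. Row index increases
# downward, so N is (-1, 0).
DIR_OFFSETS <- cbind(
  dr = c(0L, -1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
  dc = c(0L, 0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
)
rownames(DIR_OFFSETS) <- c("stay", "N", "NE", "E", "SE", "S", "SW", "W", "NW")

N_LEVELS <- 10L   # pheromone observation levels; 1 = no deposited pheromone
N_POLICIES <- 9L  # one-step relocations within the 3x3 neighborhood

#' Direction labels of the canonical 9-neighborhood
#'
#' Returns the fixed order `stay, N, NE, E, SE, S, SW, W, NW` used everywhere
#' a 9-vector indexes window cells, hidden states or policies.
#'
#' @return Character vector of length 9.
#' @export
direction_labels <- function() rownames(DIR_OFFSETS)

#' Build a T-maze arena
#'
#' Constructs the foraging environment: a grid with a T-shaped walkable
#' corridor, an integer pheromone field (levels 1--10, 1 meaning no deposited
#' pheromone), a nest at the bottom-center of the stem, food positions at the
#' distal ends of the two arms, and an alternating food schedule.
#'
#' The stem rises from the bottom row to the horizontal bar; the bar spans
#' the full grid width over `corridor_width` rows. The food cell sits at the
#' vertical middle of the bar on each side.
#'
#' @param height,width Grid dimensions in cells.
#' @param corridor_width Width of both the stem and the bar, in cells.
#' @param stem_length Length of the vertical stem in cells; by default the
#'   stem fills everything below the top bar (`height - corridor_width`).
#' @param switch_period Steps between food-arm alternations.
#' @param initial_arm Arm holding food at step 0, `"left"` or `"right"`.
#' @param horizon Nominal simulation length in steps (informational).
#' @param scent_radius Chebyshev radius within which the food and nest
#'   scents trigger; 0 means cell occupancy.
#' @return An object of class `forage_arena`: a list with `height`, `width`,
#'   `walkable` (logical matrix), `pheromone` (integer matrix), `nest`,
#'   `food_left`, `food_right` (row/col pairs), `schedule`, `scent_radius`
#'   and `time`.
#' @examples
#' ar <- build_tmaze()
#' sum(ar$walkable)
#' @export
build_tmaze <- function(height = 40L, width = 40L, corridor_width = 6L,
                        stem_length = NULL, switch_period = 500L,
                        initial_arm = c("left", "right"), horizon = 2000L,
                        scent_radius = 0L) {
  initial_arm <- match.arg(initial_arm)
  height <- as.integer(height); width <- as.integer(width)
  corridor_width <- as.integer(corridor_width)
  if (is.null(stem_length)) stem_length <- height - corridor_width
  stem_length <- as.integer(stem_length)
  if (corridor_width < 1L)
    stop("`corridor_width` must be at least 1", call. = FALSE)
  if (stem_length < 1L)
    stop("`stem_length` must be at least 1", call. = FALSE)
  if (corridor_width + stem_length > height)
    stop("T-maze does not fit: corridor_width + stem_length exceeds height",
         call. = FALSE)
  if (corridor_width > width)
    stop("T-maze does not fit: corridor_width exceeds width", call. = FALSE)
  if (switch_period < 1L)
    stop("`switch_period` must be positive", call. = FALSE)
  if (scent_radius < 0L)
    stop("`scent_radius` must be non-negative", call. = FALSE)

  bar_top <- height - stem_length - corridor_width + 1L
  bar_rows <- bar_top:(bar_top + corridor_width - 1L)
  stem_rows <- (height - stem_length + 1L):height
  stem_lo <- (width - corridor_width) %/% 2L + 1L
  stem_cols <- stem_lo:(stem_lo + corridor_width - 1L)

  walkable <- matrix(FALSE, height, width)
  walkable[bar_rows, ] <- TRUE
  walkable[stem_rows, stem_cols] <- TRUE

  food_row <- bar_rows[(corridor_width + 1L) %/% 2L]
  nest <- c(height, stem_cols[(corridor_width + 1L) %/% 2L])

  # per-cell linear indices of the 9 canonical neighbors (NA = infeasible),
  # cached so local sensing is a row lookup
  rr <- outer(rep(seq_len(height), width), DIR_OFFSETS[, 1], `+`)
  cc <- outer(rep(seq_len(width), each = height), DIR_OFFSETS[, 2], `+`)
  inside <- rr >= 1L & rr <= height & cc >= 1L & cc <= width
  nbr <- matrix(NA_integer_, height * width, N_POLICIES)
  nbr[inside] <- (cc[inside] - 1L) * height + rr[inside]
  nbr[!is.na(nbr) & !as.vector(walkable)[ifelse(is.na(nbr), 1L, nbr)]] <- NA_integer_

  structure(list(
    height = height, width = width,
    corridor_width = corridor_width, stem_length = stem_length,
    stem_cols = stem_cols,
    walkable = walkable,
    nbr = nbr,
    pheromone = matrix(1L, height, width),
    nest = nest,
    food_left = c(food_row, 1L),
    food_right = c(food_row, width),
    schedule = list(switch_period = as.integer(switch_period),
                    initial_arm = initial_arm,
                    horizon = as.integer(horizon)),
    scent_radius = as.integer(scent_radius),
    time = 0L
  ), class = "forage_arena")
}

#' @export
print.forage_arena <- function(x, ...) {
  cat(sprintf("<forage_arena> %dx%d grid, %d walkable cells\n",
              x$height, x$width, sum(x$walkable)))
  cat(sprintf("  nest (%d,%d); food L (%d,%d) R (%d,%d); switch every %d steps\n",
              x$nest[1], x$nest[2], x$food_left[1], x$food_left[2],
              x$food_right[1], x$food_right[2], x$schedule$switch_period))
  invisible(x)
}

#' Build a fully open (all-walkable) arena
#'
#' A featureless grid with every cell walkable, used to study free
#' diffusion: a flat-preference forager on an open arena performs an
#' unbiased 9-neighborhood random walk. Nest and both food positions
#' default to the top-left corner so that a walker started elsewhere is
#' effectively trigger-free.
#'
#' @param height,width Grid dimensions in cells.
#' @param nest Nest cell; also used for both food positions by default.
#' @inheritParams build_tmaze
#' @return A `forage_arena`.
#' @export
build_open_arena <- function(height = 101L, width = 101L, nest = c(1L, 1L),
                             switch_period = 500L, scent_radius = 0L) {
  height <- as.integer(height); width <- as.integer(width)
  walkable <- matrix(TRUE, height, width)
  rr <- outer(rep(seq_len(height), width), DIR_OFFSETS[, 1], `+`)
  cc <- outer(rep(seq_len(width), each = height), DIR_OFFSETS[, 2], `+`)
  inside <- rr >= 1L & rr <= height & cc >= 1L & cc <= width
  nbr <- matrix(NA_integer_, height * width, N_POLICIES)
  nbr[inside] <- (cc[inside] - 1L) * height + rr[inside]
  structure(list(
    height = height, width = width,
    corridor_width = width, stem_length = height,
    stem_cols = seq_len(width),
    walkable = walkable, nbr = nbr,
    pheromone = matrix(1L, height, width),
    nest = as.integer(nest),
    food_left = as.integer(nest), food_right = as.integer(nest),
    schedule = list(switch_period = as.integer(switch_period),
                    initial_arm = "left", horizon = NA_integer_),
    scent_radius = as.integer(scent_radius),
    time = 0L
  ), class = "forage_arena")
}

#' Environment-level reallocation matrix
#'
#' The reallocation matrix is the environment-side likelihood
#' P(pheromone level | location): one outcome distribution over the 10
#' pheromone levels per grid cell. With unbiased sensing each distribution is
#' one-hot at the cell's current level; each agent's per-step likelihood is a
#' 9-column re-cut of this matrix (see [remap_likelihood()]).
#'
#' @param arena A `forage_arena`.
#' @return A `(height*width) x 10` matrix; rows follow R's column-major
#'   linear cell index, each row summing to 1.
#' @export
make_reallocation_matrix <- function(arena) {
  stopifnot(inherits(arena, "forage_arena"))
  n <- arena$height * arena$width
  M <- matrix(0, n, N_LEVELS)
  lev <- as.vector(arena$pheromone)
  lev[!as.vector(arena$walkable)] <- 1L
  M[cbind(seq_len(n), lev)] <- 1
  M
}

#' Local 3x3 sensory window
#'
#' Reads the pheromone levels of the 9 cells around `position` in the
#' canonical order `[stay, N, NE, E, SE, S, SW, W, NW]`; index i of the
#' window is the destination of policy i. Off-grid or non-walkable
#' destinations are infeasible and report level 1.
#'
#' @param arena A `forage_arena`.
#' @param position Length-2 integer `(row, col)`, must be walkable.
#' @return List with `levels` (9 integers in 1..10) and `feasible`
#'   (9 logicals).
#' @export
local_window <- function(arena, position) {
  r <- position[1]; cc <- position[2]
  if (!arena$walkable[r, cc])
    stop("`position` is not walkable", call. = FALSE)
  idx <- arena$nbr[(cc - 1L) * arena$height + r, ]
  feas <- !is.na(idx)
  lev <- rep(1L, N_POLICIES)
  lev[feas] <- arena$pheromone[idx[feas]]
  list(levels = lev, feasible = feas)
}

#' Deposit one unit of trail pheromone
#'
#' Increments the pheromone level at `position` by one, saturating at 10.
#'
#' @param arena A `forage_arena`.
#' @param position Walkable `(row, col)` cell.
#' @return The modified arena.
#' @export
deposit_pheromone <- function(arena, position) {
  r <- position[1]; cc <- position[2]
  if (!arena$walkable[r, cc])
    stop("cannot deposit on a non-walkable cell", call. = FALSE)
  arena$pheromone[r, cc] <- min(arena$pheromone[r, cc] + 1L, N_LEVELS)
  arena
}

#' One step of stochastic pheromone decay
#'
#' Independently for every cell above baseline, with probability `p_decay`
#' the level drops by one (`mode = "decrement"`, gradual evaporation) or
#' resets to 1 (`mode = "reset"`).
#'
#' @param arena A `forage_arena`.
#' @param stream A random stream (see [rng_stream()]), or `NULL` to use the
#'   session RNG.
#' @param p_decay Per-cell per-step decay probability in `[0, 1]`.
#' @param mode `"decrement"` (default) or `"reset"`.
#' @return The modified arena.
#' @export
decay_step <- function(arena, stream = NULL, p_decay = 1e-4,
                       mode = c("decrement", "reset")) {
  mode <- match.arg(mode)
  if (!is.numeric(p_decay) || p_decay < 0 || p_decay > 1)
    stop("`p_decay` must lie in [0, 1]", call. = FALSE)
  if (p_decay == 0) return(arena)
  idx <- which(arena$pheromone > 1L)
  if (!length(idx)) return(arena)
  u <- draw_runif(length(idx), stream)
  hit <- idx[u < p_decay]
  if (length(hit)) {
    if (mode == "decrement") {
      arena$pheromone[hit] <- arena$pheromone[hit] - 1L
    } else {
      arena$pheromone[hit] <- 1L
    }
  }
  arena
}

food_arm_at <- function(schedule, t) {
  flips <- floor(t / schedule$switch_period) %% 2
  if (schedule$initial_arm == "left") {
    ifelse(flips == 0, "left", "right")
  } else {
    ifelse(flips == 0, "right", "left")
  }
}

#' Current food position under the alternating schedule
#'
#' The food sits on `initial_arm` while `floor(t / switch_period)` is even
#' and on the opposite arm otherwise, so under defaults it moves at steps
#' 500, 1,000 and 1,500.
#'
#' @param arena A `forage_arena`.
#' @param t Step index (0-based), `t >= 0`.
#' @return `(row, col)` of the food cell at step `t`.
#' @export
current_food_position <- function(arena, t) {
  stopifnot(t >= 0)
  if (food_arm_at(arena$schedule, t) == "left") arena$food_left
  else arena$food_right
}

#' Food and home scent triggers
#'
#' A scent triggers when the Chebyshev distance from `position` to the food
#' (respectively the nest) is at most `scent_radius`; the default radius 0
#' means the trigger fires on cell occupancy only.
#'
#' @param arena A `forage_arena`.
#' @param position Walkable `(row, col)`.
#' @param t Step index used to resolve the current food position.
#' @return List with logicals `food_scent` and `home_scent`.
#' @export
sense_triggers <- function(arena, position, t) {
  food <- current_food_position(arena, t)
  r <- arena$scent_radius
  cheb <- function(a, b) max(abs(a - b))
  list(food_scent = cheb(position, food) <= r,
       home_scent = cheb(position, arena$nest) <= r)
}

#' Pheromone mass on each arm
#'
#' Sums pheromone above baseline (level minus 1) over walkable cells strictly
#' left and strictly right of the stem centerline. Operationalizes the
#' visual "density locking onto one arm" readout of trail formation.
#'
#' @param arena A `forage_arena`.
#' @return Named numeric vector `c(left = , right = )`.
#' @export
arm_pheromone_mass <- function(arena) {
  centre <- (min(arena$stem_cols) + max(arena$stem_cols)) / 2
  excess <- (arena$pheromone - 1L) * arena$walkable
  cols <- col(excess)
  c(left = sum(excess[cols < centre]), right = sum(excess[cols > centre]))
}

#' Write the pheromone field as a plain-text integer grid
#'
#' One grid row per line, space-delimited, suitable for diffing and for
#' reloading with [read_field_grid()].
#'
#' @param field Integer matrix (e.g. `arena$pheromone` or a snapshot).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_grid <- function(field, path) {
  utils::write.table(field, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_field_grid
#' @export
read_field_grid <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}
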