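# Orchestration of a full run: configuration, seeding, the step loop
# (food switching, per-agent updates, decay), and recording of
# trajectories, metric series and field snapshots.

#' Simulation configuration
#'
#' Collects and validates everything that determines a run. The defaults
#' reproduce the reference setup: a 40x40 T-maze, 2,000 steps, food
#' alternating every 500 steps, per-cell decay probability 0.01, strict
#' pheromone preferences, and softmax action sampling.
#'
#' @param n_ants Colony size (typical sizes: 10, 30, 50, 70).
#' @param n_steps Number of steps of action and inference per ant.
#' @param switch_period Steps between food-arm switches.
#' @param p_decay Per-cell per-step pheromone decay probability. The
#'   default 0.01 lets a stale trail fade over a few hundred steps, the
#'   timescale on which the colony re-locks onto the newly rewarded arm;
#'   set 1e-4 for near-permanent trails.
#' @param preference `"strict"` or `"flat"` pheromone preferences.
#' @param alpha Strict-preference slope.
#' @param gamma Policy precision.
#' @param kappa Laden homing-bias weight. The default 3 makes homeward
#'   travel nearly direct; smaller values leave laden foragers lingering on
#'   their own freshly laid trail.
#' @param scent_radius Chebyshev trigger radius for food/home scents.
#' @param height,width,corridor_width,stem_length T-maze geometry
#'   (see [build_tmaze()]).
#' @param initial_arm Arm holding food at step 0.
#' @param master_seed Integer master seed; all randomness derives from it.
#' @param snapshot_every Record a pheromone-field snapshot every this many
#'   steps (0 disables snapshots).
#' @param action_mode `"sample"` (stochastic softmax draw) or `"argmax"`.
#' @param update_order `"sequential"` (agents move in id order within a
#'   step, deposits immediately visible to later agents) or
#'   `"synchronous"` (all agents sense the start-of-step field, deposits
#'   applied afterwards).
#' @param decay_mode `"decrement"` or `"reset"` (see [decay_step()]).
#' @return A validated list of class `forage_config`.
#' @export
sim_config <- function(n_ants = 30L, n_steps = 2000L, switch_period = 500L,
                       p_decay = 0.01, preference = "strict", alpha = 0.5,
                       gamma = 1, kappa = 3, scent_radius = 0L,
                       height = 40L, width = 40L, corridor_width = 6L,
                       stem_length = NULL, initial_arm = "left",
                       master_seed = 1L, snapshot_every = 50L,
                       action_mode = "sample",
                       update_order = "sequential",
                       decay_mode = "decrement") {
  cfg <- list(n_ants = as.integer(n_ants), n_steps = as.integer(n_steps),
              switch_period = as.integer(switch_period),
              p_decay = p_decay, preference = preference, alpha = alpha,
              gamma = gamma, kappa = kappa,
              scent_radius = as.integer(scent_radius),
              height = as.integer(height), width = as.integer(width),
              corridor_width = as.integer(corridor_width),
              stem_length = if (is.null(stem_length)) NULL
                            else as.integer(stem_length),
              initial_arm = initial_arm,
              master_seed = as.integer(master_seed),
              snapshot_every = as.integer(snapshot_every),
              action_mode = action_mode, update_order = update_order,
              decay_mode = decay_mode)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  bad <- function(key, why) stop(sprintf("config key `%s`: %s", key, why),
                                 call. = FALSE)
  if (cfg$n_ants < 1L) bad("n_ants", "must be a positive count")
  if (cfg$n_steps < 0L) bad("n_steps", "must be non-negative")
  if (cfg$switch_period < 1L) bad("switch_period", "must be positive")
  if (!is.numeric(cfg$p_decay) || cfg$p_decay < 0 || cfg$p_decay > 1)
    bad("p_decay", "must lie in [0, 1]")
  if (!cfg$preference %in% c("strict", "flat"))
    bad("preference", "must be 'strict' or 'flat'")
  if (cfg$preference == "strict" && cfg$alpha <= 0)
    bad("alpha", "must be positive for strict preferences")
  if (cfg$gamma <= 0) bad("gamma", "must be positive")
  if (cfg$kappa < 0) bad("kappa", "must be non-negative")
  if (cfg$scent_radius < 0L) bad("scent_radius", "must be non-negative")
  if (cfg$snapshot_every < 0L) bad("snapshot_every", "must be non-negative")
  if (!cfg$action_mode %in% c("sample", "argmax"))
    bad("action_mode", "must be 'sample' or 'argmax'")
  if (!cfg$update_order %in% c("sequential", "synchronous"))
    bad("update_order", "must be 'sequential' or 'synchronous'")
  if (!cfg$decay_mode %in% c("decrement", "reset"))
    bad("decay_mode", "must be 'decrement' or 'reset'")
  if (!cfg$initial_arm %in% c("left", "right"))
    bad("initial_arm", "must be 'left' or 'right'")
  # geometry errors surface from build_tmaze with the offending key
  structure(cfg, class = "forage_config")
}

arena_from_config <- function(cfg) {
  build_tmaze(height = cfg$height, width = cfg$width,
              corridor_width = cfg$corridor_width,
              stem_length = cfg$stem_length,
              switch_period = cfg$switch_period,
              initial_arm = cfg$initial_arm, horizon = cfg$n_steps,
              scent_radius = cfg$scent_radius)
}

#' Run a full colony simulation
#'
#' All ants start at the nest. Per step t (0-based): the food position is
#' resolved from the schedule; each forager performs one cycle of action
#' and inference (in fixed id order under sequential updating, with
#' within-step deposits immediately visible to later-indexed agents); the
#' field decays; positions, metrics and (periodically) field snapshots are
#' recorded.
#'
#' @param config A `forage_config` from [sim_config()].
#' @param progress Print a summary line every 500 steps.
#' @return An object of class `forage_sim`: list with `config`,
#'   `trajectories` (tibble: step, id, row, col, laden, round_trips),
#'   `metrics` (tibble: step, food_arm, distance_coefficient,
#'   cumulative_round_trips, left_arm_mass, right_arm_mass), `snapshots`
#'   (named list of integer fields), `final_field`, `walkable`, `arena`.
#' @examples
#' sim <- run_simulation(sim_config(n_ants = 5, n_steps = 50))
#' sim$metrics
#' @export
run_simulation <- function(config, progress = FALSE) {
  if (!inherits(config, "forage_config")) config <- do.call(sim_config, config)
  cfg <- config
  arena <- arena_from_config(cfg)
  model <- make_generative_model(preference = cfg$preference,
                                 alpha = cfg$alpha, gamma = cfg$gamma,
                                 kappa = cfg$kappa,
                                 action_mode = cfg$action_mode)
  env_stream <- derive_agent_stream(cfg$master_seed, 0L)
  foragers <- lapply(seq_len(cfg$n_ants), function(i)
    new_forager(i, arena$nest, derive_agent_stream(cfg$master_seed, i)))

  n <- cfg$n_steps
  na <- cfg$n_ants
  row_m <- matrix(NA_integer_, n, na); col_m <- row_m
  laden_m <- matrix(NA, n, na); trips_m <- matrix(NA_integer_, n, na)
  left_mass <- numeric(n); right_mass <- numeric(n)
  food_arm <- character(n)
  snapshots <- list()

  for (t0 in seq_len(n) - 1L) {
    arena$time <- t0
    food_arm[t0 + 1L] <- food_arm_at(arena$schedule, t0)
    if (cfg$update_order == "sequential") {
      for (i in seq_len(na)) {
        out <- step_forager(foragers[[i]], arena, model)
        foragers[[i]] <- out$forager
        arena <- out$arena
      }
    } else {
      frozen <- arena
      deposits <- integer(0)
      for (i in seq_len(na)) {
        frozen$pheromone <- arena$pheromone  # pre-step field for sensing
        was_laden <- foragers[[i]]$laden
        out <- step_forager(foragers[[i]], frozen, model)
        foragers[[i]] <- out$forager
        if (was_laden)
          deposits <- c(deposits,
                        (out$forager$position[2] - 1L) * arena$height +
                          out$forager$position[1])
      }
      for (idx in deposits)
        arena$pheromone[idx] <- min(arena$pheromone[idx] + 1L, N_LEVELS)
    }
    arena <- decay_step(arena, env_stream, p_decay = cfg$p_decay,
                        mode = cfg$decay_mode)
    for (i in seq_len(na)) {
      row_m[t0 + 1L, i] <- foragers[[i]]$position[1]
      col_m[t0 + 1L, i] <- foragers[[i]]$position[2]
      laden_m[t0 + 1L, i] <- foragers[[i]]$laden
      trips_m[t0 + 1L, i] <- foragers[[i]]$round_trips
    }
    mass <- arm_pheromone_mass(arena)
    left_mass[t0 + 1L] <- mass[["left"]]
    right_mass[t0 + 1L] <- mass[["right"]]
    if (cfg$snapshot_every > 0L && t0 %% cfg$snapshot_every == 0L)
      snapshots[[as.character(t0)]] <- arena$pheromone
    if (progress && (t0 + 1L) %% 500L == 0L)
      message(sprintf("step %d: %d round trips, arm mass L=%g R=%g",
                      t0 + 1L, sum(trips_m[t0 + 1L, ]),
                      mass[["left"]], mass[["right"]]))
  }

  dc <- vapply(seq_len(n), function(k)
    distance_coefficient(cbind(row = row_m[k, ], col = col_m[k, ])),
    numeric(1))

  trajectories <- tibble::tibble(
    step = rep(seq_len(n) - 1L, each = na),
    id = rep(seq_len(na), n),
    row = as.integer(t(row_m)), col = as.integer(t(col_m)),
    laden = as.logical(t(laden_m)),
    round_trips = as.integer(t(trips_m)))
  metrics <- tibble::tibble(
    step = seq_len(n) - 1L,
    food_arm = food_arm,
    distance_coefficient = dc,
    cumulative_round_trips = as.integer(rowSums(trips_m)),
    left_arm_mass = left_mass, right_arm_mass = right_mass)

  structure(list(config = cfg, trajectories = trajectories,
                 metrics = metrics, snapshots = snapshots,
                 final_field = arena$pheromone,
                 walkable = arena$walkable, arena = arena),
            class = "forage_sim")
}

#' @export
print.forage_sim <- function(x, ...) {
  cat(sprintf("<forage_sim> %d ants, %d steps, %s preferences, seed %d\n",
              x$config$n_ants, x$config$n_steps, x$config$preference,
              x$config$master_seed))
  if (nrow(x$metrics)) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  round trips: %d; final DC: %.1f; arm mass L=%g R=%g\n",
                last$cumulative_round_trips, last$distance_coefficient,
                last$left_arm_mass, last$right_arm_mass))
  }
  invisible(x)
}

#' Sweep colony sizes and seeds
#'
#' Runs one simulation per (colony size, seed) pair and row-binds per-step
#' metrics into one tidy table.
#'
#' @param sizes Integer vector of colony sizes.
#' @param seeds Integer vector of master seeds.
#' @param ... Further arguments passed to [sim_config()].
#' @return Tibble: the per-step metrics of every run with `n_ants` and
#'   `master_seed` columns prepended.
#' @export
sweep_colony_sizes <- function(sizes = c(10L, 30L, 50L, 70L), seeds = 1L,
                               ...) {
  grid <- tidyr::expand_grid(n_ants = as.integer(sizes),
                             master_seed = as.integer(seeds))
  purrr::pmap_dfr(grid, function(n_ants, master_seed) {
    sim <- run_simulation(sim_config(n_ants = n_ants,
                                     master_seed = master_seed, ...))
    dplyr::mutate(sim$metrics, n_ants = n_ants, master_seed = master_seed,
                  .before = 1)
  })
}
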