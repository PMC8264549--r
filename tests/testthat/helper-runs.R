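# Cache of full-length colony runs shared by the acceptance blocks, so each
# (config, seed) pair is simulated once per test session.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(n_ants, seed, preference = "strict") {
  key <- sprintf("%d_%d_%s", n_ants, seed, preference)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_simulation(
      sim_config(n_ants = n_ants, master_seed = seed,
                 preference = preference, snapshot_every = 0L))
  }
  .run_cache[[key]]
}

# the switching signature: after the first food move (step 500), does the
# newly food-bearing arm's pheromone mass exceed the stale arm's by step 1000?
switch_signature <- function(sim) {
  m <- sim$metrics
  m$right_arm_mass[1000] > m$left_arm_mass[1000]
}
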