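# Small, fast scenarios used across the suite.

# Compact possum-like block: 10 x 6 traps at 50 x 100 m, 100 m buffer.
small_layout <- function(buffer = 100) {
  layout_spec(50, 100, 10, 6, buffer = buffer)
}

small_scenario <- function(density = 1, capacity = 1, nights = 30,
                           replicates = 20, seed = 42, ...) {
  scenario_config(detection_params(0.05, 63), small_layout(),
                  density = density, capacity = capacity, nights = nights,
                  replicates = replicates, seed = seed, ...)
}

# A set of mutually isolated animal-trap pairs: traps spaced far beyond the
# truncation radius, one animal at distance `d` from each trap.  Each pair
# is then an independent Bernoulli trial with p = capture_probability(d),
# which gives an analytic oracle for the capture kernels.
isolated_pairs <- function(n_pairs, d, params = detection_params(0.05, 63),
                           capacity = 1, truncation = 5) {
  spacing <- 4 * truncation * params$sigma
  lay <- layout_spec(spacing, spacing, n_pairs, 1, buffer = 0,
                     buffered_area = 1)  # placement area unused: animals are placed by hand
  grid <- build_trap_grid(lay, capacity = capacity)
  centres <- grid$positions
  centres[, 1] <- centres[, 1] + d
  pop <- population_state(centres)
  list(layout = lay, grid = grid, pop = pop, params = params,
       table = build_encounter_table(grid, pop, params, truncation))
}

# Mean population kill over `reps` replicates.
mean_kill <- function(cfg, reps = cfg$replicates) {
  population_capture_proportion(trap_sim(cfg, replicates = reps))$mean
}

preset_layout <- function(species) species_preset(species)$layout
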