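test_that("the per-trap distribution counts directly", {
  # a single replicate with counts [0, 1, 1]
  d <- trap_capture_distribution(matrix(c(0L, 1L, 1L), ncol = 1), capacity = 2)
  expect_equal(d$proportion, c(1 / 3, 2 / 3, 0))
  expect_equal(d$ge_proportion, c(1, 2 / 3, 0))
  expect_equal(attr(d, "any_capture"), 2 / 3)
  # all traps empty
  empty <- trap_capture_distribution(matrix(0L, 5, 3), capacity = 1)
  expect_equal(empty$proportion, c(1, 0))
  expect_error(trap_capture_distribution(matrix(integer(0), 3, 0)),
               "replicate")
})

test_that("distribution rows always sum to one", {
  set.seed(41)
  for (i in 1:10) {
    capacity <- sample(c(1, 2, 6, 12), 1)
    m <- matrix(sample(0:capacity, 60, replace = TRUE), 20, 3)
    d <- trap_capture_distribution(m, capacity = capacity)
    expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
    expect_true(all(d$sd >= 0))
  }
})

test_that("summaries accept raw replicate results as well as trap_sim objects", {
  cfg <- small_scenario(density = 2, capacity = 2)
  reps <- lapply(1:4, function(r) simulate_replicate(cfg, r))
  d <- trap_capture_distribution(reps, capacity = 2)
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
  p <- population_capture_proportion(reps)
  expect_equal(p$mean, mean(vapply(reps, function(r) r$captured / r$exposed,
                                   numeric(1))))
})

test_that("population proportion uses the exposed denominator", {
  cfg <- small_scenario(density = 1, replicates = 5)
  fit <- trap_sim(cfg)
  p <- population_capture_proportion(fit)
  expect_equal(p$mean, mean(fit$captured / fit$exposed))
  expect_true(p$mean >= 0 && p$mean <= 1)
  expect_equal(p$replicates, 5)
  # certain capture: one animal sitting on a dense block of strong traps
  sure <- scenario_config(detection_params(0.9, 63),
                          layout_spec(20, 20, 5, 5, buffer = 0,
                                      buffered_area = 1 / 2500),
                          density = 2500, nights = 30, replicates = 3,
                          seed = 1)
  expect_equal(population_capture_proportion(trap_sim(sure))$mean, 1)
  # zero exposed animals is undefined
  none <- trap_sim(small_scenario(density = 0, replicates = 2))
  expect_error(population_capture_proportion(none), "exposed")
})

test_that("a 1x1 sweep equals the single scenario run at the cell seed", {
  cfg <- small_scenario(density = 2, capacity = 2, replicates = 8)
  sweep <- density_sweep(cfg, densities = 2, capacities = 2)
  cfg$seed <- cell_seed(cfg$seed, 1, 1)
  fit <- trap_sim(cfg)
  pop_row <- sweep[sweep$metric == "population", ]
  expect_equal(pop_row$mean, population_capture_proportion(fit)$mean)
  d <- trap_capture_distribution(fit)
  k_rows <- sweep[sweep$metric == "traps_with_k", ]
  expect_equal(k_rows$mean, d$proportion)
})

test_that("sweep output is monotone where saturation theory demands", {
  cfg <- small_scenario(density = 1, replicates = 30, seed = 5)
  sweep <- density_sweep(cfg, densities = c(1, 4), capacities = c(1, 3, 6))
  pop <- sweep[sweep$metric == "population", ]
  for (dens in unique(pop$density)) {
    col <- pop[pop$density == dens, ]
    col <- col[order(col$capacity), ]
    expect_true(all(diff(col$mean) >= -1e-9))
  }
  any_ <- sweep[sweep$metric == "traps_any" & sweep$capacity == 1, ]
  any_ <- any_[order(any_$density), ]
  expect_true(all(diff(any_$mean) >= 0))
})

test_that("ample capacity approaches the no-saturation limit", {
  cfg <- small_scenario(density = 3, capacity = 1, replicates = 25, seed = 6)
  pop_n <- round(cfg$density * cfg$layout$buffered_area)
  unconstrained <- cfg
  unconstrained$capacity <- as.integer(pop_n)  # every trap can absorb everyone
  big <- cfg; big$capacity <- 12L
  expect_lt(abs(mean_kill(big) - mean_kill(unconstrained)), 0.02)
})
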