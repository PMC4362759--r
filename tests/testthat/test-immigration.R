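test_that("the nightly schedule carries fractions and sums exactly", {
  s <- immigrant_schedule(12628, 30)
  expect_equal(sum(s), 12628)
  expect_true(all(s %in% c(420L, 421L)))
  expect_equal(immigrant_schedule(0, 30), rep(0L, 30))
  expect_equal(immigrant_schedule(30, 30), rep(1L, 30))
  set.seed(31)
  for (i in 1:20) {
    total <- sample.int(5000, 1); nights <- sample.int(60, 1)
    s <- immigrant_schedule(total, nights)
    expect_equal(sum(s), total)
    expect_lte(diff(range(s)), 1)
  }
})

test_that("zone assignment follows the perimeter-weighted frequencies", {
  spec <- immigration_spec()
  expect_identical(assign_zones(0, spec), integer(0))
  all_outer <- immigration_spec(zone_weights = c(1, 0, 0))
  expect_true(all(assign_zones(500, all_outer) == 1L))
  set.seed(32)
  z <- assign_zones(10000, spec)
  expect_lt(abs(mean(z == 1) - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))
  expect_lt(abs(mean(z == 2) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  expect_error(immigration_spec(zone_weights = c(0.6, 0.3, 0.3)), "sum to 1")
})

test_that("immigrants land inside their own zone frames", {
  lay <- preset_layout("rat")
  spec <- immigration_spec()
  step <- min(lay$width, lay$height) / 6
  edge_dist <- function(m) pmin(m[, 1], m[, 2], lay$width - m[, 1],
                                lay$height - m[, 2])
  set.seed(33)
  for (z in 1:3) {
    pts <- place_immigrants(rep(z, 400), lay, spec)
    expect_true(all(pts$origin == "immigrant"))
    expect_true(all(pts$status == "at-large"))
    d <- edge_dist(pts$centres)
    expect_true(all(d >= (z - 1) * step - 1e-9))
    if (z < 3) expect_true(all(d < z * step + 1e-9))
  }
})

test_that("placement is uniform within the inner zone", {
  lay <- preset_layout("rat")
  spec <- immigration_spec()
  step <- min(lay$width, lay$height) / 6
  set.seed(34)
  pts <- place_immigrants(rep(3, 6000), lay, spec)$centres
  # the inner zone is the central rectangle; chi-square over a 4 x 4 grid
  gx <- cut(pts[, 1], seq(2 * step, lay$width - 2 * step, length.out = 5))
  gy <- cut(pts[, 2], seq(2 * step, lay$height - 2 * step, length.out = 5))
  expect_gt(chisq.test(table(gx, gy))$p.value, 1e-3)
})

test_that("a full run introduces exactly the configured immigrants", {
  cfg <- small_scenario(density = 1, replicates = 2,
                        immigration = immigration_spec(total = 57))
  rep1 <- simulate_replicate(cfg, 1)
  expect_equal(rep1$n_immigrants, 57)
  expect_equal(sum(rep1$fates$origin == "immigrant"), 57)
  expect_equal(rep1$exposed, rep1$n_residents + 57)
  # immigrants are never captured before their arrival night
  imm <- rep1$fates[rep1$fates$origin == "immigrant", ]
  caught <- !is.na(imm$night)
  expect_true(all(imm$night[caught] >= imm$entry_night[caught]))
  # default total equals the initial resident population
  cfg2 <- small_scenario(density = 1, immigration = immigration_spec())
  rep2 <- simulate_replicate(cfg2, 1)
  expect_equal(rep2$n_immigrants, rep2$n_residents)
})

test_that("zero immigration is bit-identical to a closed population", {
  closed <- small_scenario(density = 1.5, capacity = 2, seed = 77)
  zero <- small_scenario(density = 1.5, capacity = 2, seed = 77,
                         immigration = immigration_spec(total = 0))
  a <- simulate_replicate(closed, 2)
  b <- simulate_replicate(zero, 2)
  expect_identical(a$trap_counts, b$trap_counts)
  expect_identical(a$fates[c("night", "trap")], b$fates[c("night", "trap")])
})
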