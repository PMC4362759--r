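test_that("cost components follow the itemised formula and sum to the total", {
  a24 <- trap_cost_spec(140, 5, 3, model = "A24")
  lab <- labour_spec(daily_rate = 300, minutes_per_day = 480, n_checks = 1)
  cost <- cost_per_hectare(a24, lab, n_sites = 84, area = 1040)
  expect_equal(cost$hardware, 140 * 84 / 1040)
  expect_equal(cost$labour, (5 + 3) * 84 / 480 * 300 / 1040)
  expect_equal(cost$hardware + cost$labour, cost$total)
  # degenerate free trapping
  free <- cost_per_hectare(trap_cost_spec(0, 5, 2),
                           labour_spec(daily_rate = 0), 100, 50)
  expect_equal(free$total, 0)
  expect_error(cost_per_hectare(a24, lab, 84, 0), "area")
})

test_that("itemisation additivity holds across random specs", {
  set.seed(51)
  for (i in 1:20) {
    trap <- trap_cost_spec(runif(1, 0, 200), runif(1, 0, 10), runif(1, 0, 10),
                           traps_per_site = sample.int(6, 1))
    lab <- labour_spec(runif(1, 1, 500), runif(1, 200, 600),
                       n_checks = sample(0:4, 1), exchange_rate = runif(1, 0.3, 2))
    cost <- cost_per_hectare(trap, lab, sample.int(5000, 1), runif(1, 10, 2000))
    expect_equal(cost$hardware + cost$labour, cost$total, tolerance = 1e-12)
  }
})

test_that("costs scale linearly and are homogeneous in sites over area", {
  trap <- trap_cost_spec(24, 5, 2)
  lab <- labour_spec()
  one <- cost_per_hectare(trap, lab, 100, 10)
  trap2 <- trap; trap2$traps_per_site <- 2L
  two <- cost_per_hectare(trap2, lab, 100, 10)
  expect_equal(two$hardware, 2 * one$hardware)
  expect_equal(two$labour, 2 * one$labour)
  both <- cost_per_hectare(trap, lab, 200, 20)
  expect_equal(both$total, one$total)
})

test_that("strategy comparison finds cost parity near five Sentinels per A12", {
  sentinel <- trap_cost_spec(24, 5, 2, model = "Sentinel")
  a12 <- trap_cost_spec(140, 5, 3, model = "A12")
  lab <- labour_spec(daily_rate = 300, minutes_per_day = 480, n_checks = 1)
  tab <- strategy_compare(sentinel, a12, lab, n_sites = 2106, area = 1140,
                          max_traps_per_site = 8)
  singles <- tab[tab$strategy != "multi", ]
  multi <- tab[tab$strategy == "multi", ]
  # totals rise monotonically with traps per site
  expect_true(all(diff(singles$total) > 0))
  # hardware alone crosses the A12 price between five and six traps
  expect_equal(min(which(singles$traps_per_site * 24 >= 140)), 6)
  # with labour included, parity sits at five per site
  expect_equal(singles$traps_per_site[which.min(abs(singles$total - multi$total))],
               5)
  # a free single trap dominates at every count
  free <- trap_cost_spec(0, 0, 0)
  tab0 <- strategy_compare(free, a12, lab, 100, 100, 6)
  expect_true(all(tab0$total[tab0$strategy != "multi"] <
                  tab0$total[tab0$strategy == "multi"]))
})

test_that("shipped cost presets load with the indicative prices", {
  p <- trap_cost_presets()
  expect_setequal(p$traps$price, c(24, 140, 6.3, 38))
  expect_s3_class(p$labour, "labour_spec")
  expect_equal(p$labour$daily_rate, 300)
})
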