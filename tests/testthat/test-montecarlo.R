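test_that("a seeded simulation is exactly reproducible", {
  pair <- grid_pair(cycles = 3, d = 0.05)
  a <- run_simulation(pair, default_config, n = 25, seed = 123)
  b <- run_simulation(pair, default_config, n = 25, seed = 123)
  expect_identical(a, b)
  c2 <- run_simulation(pair, default_config, n = 25, seed = 124)
  expect_false(identical(a$iterations$delta, c2$iterations$delta))
})

test_that("iteration i is the same lane whatever the batch size", {
  pair <- grid_pair(cycles = 2, d = 0.03)
  big <- run_simulation(pair, default_config, n = 40, seed = 9)
  one <- run_iteration(pair, default_config, iteration = 17, seed = 9)
  expect_equal(one$npv_bse, big$iterations$npv_bse[17])
  expect_equal(one$delta, big$iterations$delta[17])
})

test_that("identical strategies under shared substreams tie exactly", {
  res <- run_simulation(null_pair(), default_config, n = 30, seed = 5,
                        common_random_numbers = TRUE)
  expect_true(all(res$iterations$delta == 0))
  expect_equal(res$p_positive, 0) # ties count as not positive
})

test_that("with no stochastic events the delta is the deterministic gap", {
  cfg <- default_config
  pair <- strategy_pair(
    bse = deterministic_strategy(TRUE, 0.66),
    nbse = deterministic_strategy(FALSE, 0.54),
    cycles = 2, label = "det"
  )
  res <- run_simulation(pair, cfg, n = 3, seed = 1)
  expect_equal(var(res$iterations$delta), 0)
  expect_true(res$p_positive %in% c(0, 1))

  # independent composition from the economics layer
  sim <- cfg$simulation
  bh <- bulls_required(sim$herd_size, 25)
  gap_by_year <- function(f) {
    m <- simulate_reproduction(sim$herd_size, 2, f, sim$horizon)
    rev <- calf_revenue_by_year(m, cfg$budget, cfg$prices,
                                sim$abortion_rate, sim$calf_death_loss)
    open <- sim$herd_size - rowSums(m)
    rev + cull_revenue(open, cfg$budget$cow_cull_weight,
                       cfg$budget$cow_cull_price) -
      open * cfg$budget$heifer_purchase_price
  }
  net_bse <- gap_by_year(0.66) -
    bull_maintenance(bh, strategy_config(TRUE), cfg$budget)
  net_nbse <- gap_by_year(0.54) -
    bull_maintenance(bh, strategy_config(FALSE), cfg$budget)
  expected_delta <- npv(net_bse, sim$discount_rate)$npv -
    npv(net_nbse, sim$discount_rate)$npv
  expect_equal(res$iterations$delta[1], expected_delta, tolerance = 1e-9)
  expect_gt(expected_delta, 0) # the fertility gap dwarfs the fee annuity
})

test_that("exchangeable null strategies split dNPV evenly", {
  res <- run_simulation(null_pair(), default_config, n = 2000, seed = 42)
  se3 <- 3 * sqrt(0.25 / 2000)
  expect_lt(abs(res$p_positive - 0.5), se3)
})

test_that("indifference points interpolate the 50% crossing", {
  expect_equal(indifference_point(c(0, 0.01, 0.02), c(0.2, 0.5, 0.9))$value,
               0.01)
  ip <- indifference_point(c(0, 0.01), c(0.4, 0.6))
  expect_equal(ip$status, "crossing")
  expect_equal(ip$value, 0.005)
  expect_equal(indifference_point(c(0, 0.01), c(0.6, 0.9))$status,
               "below_grid")
  expect_equal(indifference_point(c(0, 0.01), c(0.1, 0.2))$status,
               "above_grid")
  expect_warning(
    ip2 <- indifference_point(seq(0, 0.03, 0.01), c(0.4, 0.6, 0.4, 0.8)),
    "more than once")
  expect_equal(ip2$value, 0.005)
})

test_that("a reduced sweep reproduces the qualitative orderings", {
  grid <- scenario_grid(cycles = c(2, 6), fertility_diff = c(0, 0.06, 0.12))
  sw <- sweep_scenarios(default_config, grid, n = 150, seed = 77)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 12)
  expect_true(all(sw$p_positive >= 0 & sw$p_positive <= 1))
  tol <- 3 * sqrt(0.25 / 150)
  for (p in unique(sw$pairing)) {
    for (K in unique(sw$cycles)) {
      cur <- sw[sw$pairing == p & sw$cycles == K, ]
      cur <- cur[order(cur$fertility_diff), ]
      expect_true(all(diff(cur$p_positive) >= -tol)) # non-decreasing in d
    }
  }
  wide <- merge(sw[sw$pairing == "25:25", ], sw[sw$pairing == "33:25", ],
                by = c("cycles", "fertility_diff"))
  expect_true(all(wide$p_positive.y >= wide$p_positive.x - tol))
  # BSE strictly costlier at equal fertility and ratio
  expect_lt(sw$p_positive[sw$pairing == "25:25" & sw$cycles == 2 &
                            sw$fertility_diff == 0], 0.5)
  # large fertility gap at a short season: BSE dominant
  expect_gt(sw$p_positive[sw$pairing == "25:25" & sw$cycles == 2 &
                            sw$fertility_diff == 0.12], 0.95)
})

test_that("indifference table summarises each curve of a sweep", {
  grid <- scenario_grid(cycles = 2, fertility_diff = seq(0, 0.12, 0.02))
  sw <- sweep_scenarios(default_config, grid, n = 200, seed = 3)
  it <- indifference_table(sw)
  expect_equal(nrow(it), 2)
  expect_setequal(it$pairing, c("25:25", "33:25"))
  ok <- it$status == "crossing"
  expect_true(all(it$indifference_diff[ok] >= 0 &
                    it$indifference_diff[ok] <= 0.12))
})

test_that("the culling audit logs one iteration per strategy-year", {
  pair <- grid_pair(cycles = 3, d = 0.05)
  log <- audit_culls(pair, default_config, seed = 11)
  expect_equal(nrow(log), 2 * default_config$simulation$horizon)
  expect_setequal(unique(log$strategy), c("BSE", "NBSE"))
  expect_true(all(log$bulls_test_fail[log$strategy == "NBSE"] == 0))
  expect_true(all(log$bulls_injury + log$bulls_test_fail + log$bulls_age <= 40))
})
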