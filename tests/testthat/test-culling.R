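test_that("binomial draws respect their support and moments", {
  expect_identical(draw_binomial(40, 0, n = 5), rep(0L, 5))
  expect_identical(draw_binomial(40, 1, n = 5), rep(40L, 5))
  expect_error(draw_binomial(40, 1.2), "\\[0, 1\\]")
  expect_error(draw_binomial(-1, 0.5), "non-negative")
  set.seed(101)
  x <- draw_binomial(40, 0.25, n = 1e5)
  expect_lt(abs(mean(x) - 10), 0.1)
  expect_lt(abs(var(x) - 7.5) / 7.5, 0.05)
})

test_that("the bull cascade culls sequentially and within the battery", {
  bse <- strategy_config(uses_bse = TRUE)
  nbse <- strategy_config(uses_bse = FALSE)
  z <- bull_cull_cascade(0, bse, n = 10)
  expect_true(all(z == 0))
  set.seed(7)
  d <- bull_cull_cascade(40, bse, n = 2000)
  expect_true(all(rowSums(d) <= 40))
  expect_true(all(d >= 0))
  set.seed(7)
  d_nbse <- bull_cull_cascade(40, nbse, n = 2000)
  expect_true(all(d_nbse$test_fail == 0))
})

test_that("closed-form cull moments match the cascade construction", {
  bse <- strategy_config(uses_bse = TRUE)
  nbse <- strategy_config(uses_bse = FALSE)
  e_bse <- expected_bull_culls(40, bse)
  e_nbse <- expected_bull_culls(40, nbse)
  # stage-by-stage means: 40*.1 + 36*.2 + 28.8*.25 and 40*.05 + 38*.25
  expect_equal(e_bse$mean, 18.4)
  expect_equal(e_nbse$mean, 11.5)
  expect_equal(e_bse$variance_stagewise,
               40 * .1 * .9 + 36 * .2 * .8 + 28.8 * .25 * .75)
  # exact total: every bull survives all events independently
  expect_equal(e_bse$variance, 40 * 0.46 * 0.54)
  zero <- strategy_config(TRUE, p_injury_cull = 0, p_test_fail = 0,
                          p_age_cull = 0)
  expect_equal(expected_bull_culls(25, zero)$mean, 0)
  expect_equal(expected_bull_culls(25, zero)$variance, 0)
  expect_gt(e_bse$mean, e_nbse$mean) # screening culls more bulls
})

test_that("simulated cascade moments agree with the exact closed form", {
  bse <- strategy_config(uses_bse = TRUE)
  e <- expected_bull_culls(40, bse)
  set.seed(11)
  totals <- rowSums(bull_cull_cascade(40, bse, n = 1e5))
  expect_lt(abs(mean(totals) - e$mean) / e$mean, 0.01)
  expect_lt(abs(var(totals) - e$variance) / e$variance, 0.01)
})

test_that("cascade totals match brute-force enumeration (total variation)", {
  bse <- strategy_config(uses_bse = TRUE)
  bh <- 10
  # enumerate all (injury, test, age) paths of the sequential cascade
  pmf <- numeric(bh + 1)
  for (i in 0:bh) {
    for (tf in 0:(bh - i)) {
      for (a in 0:(bh - i - tf)) {
        p <- dbinom(i, bh, bse$p_injury_cull) *
          dbinom(tf, bh - i, bse$p_test_fail) *
          dbinom(a, bh - i - tf, bse$p_age_cull)
        pmf[i + tf + a + 1] <- pmf[i + tf + a + 1] + p
      }
    }
  }
  expect_equal(sum(pmf), 1)
  set.seed(23)
  totals <- rowSums(bull_cull_cascade(bh, bse, n = 1e5))
  emp <- tabulate(totals + 1, nbins = bh + 1) / 1e5
  tv <- 0.5 * sum(abs(pmf - emp))
  expect_lt(tv, 0.01)
})

test_that("cow culls split open (deterministic) from non-reproductive", {
  cc <- cow_culls(1000, 884.4, p_nr = 0.1, n = 1)
  expect_equal(cc$open, 115.6)
  expect_true(cc$nonreproductive >= 0 && cc$nonreproductive <= 884)
  expect_equal(cow_culls(1000, 1000, 0.1)$open, 0)
  expect_identical(cow_culls(1000, 884.4, 0)$nonreproductive, 0L)
  set.seed(31)
  many <- cow_culls(1000, 884.4, 0.1, n = 5e4)$nonreproductive
  expect_lt(abs(mean(many) - 88.4), 0.5)
  expect_error(cow_culls(1000, 1001, 0.1))
})

test_that("mortality draws are bounded and average at the rates", {
  s <- strategy_config(uses_bse = FALSE)
  zero <- strategy_config(FALSE, p_cow_mortality = 0, p_bull_mortality = 0)
  md0 <- mortality_draws(1000, 40, zero, n = 10)
  expect_true(all(md0$cow_deaths == 0) && all(md0$bull_deaths == 0))
  set.seed(41)
  md <- mortality_draws(1000, 40, s, n = 5e4)
  expect_true(all(md$cow_deaths <= 1000) && all(md$bull_deaths <= 40))
  expect_lt(abs(mean(md$cow_deaths) - 10), 0.1)
  expect_lt(abs(mean(md$bull_deaths) - 0.4), 0.02)
})

test_that("substream seeds are deterministic, distinct, and in range", {
  a <- substream_seed(1, "scenario1", "bse", 3, "injury")
  b <- substream_seed(1, "scenario1", "bse", 3, "injury")
  expect_identical(a, b)
  expect_false(a == substream_seed(1, "scenario1", "nbse", 3, "injury"))
  expect_false(a == substream_seed(2, "scenario1", "bse", 3, "injury"))
  expect_false(substream_seed(1, "ab", "c") == substream_seed(1, "a", "bc"))
  seeds <- vapply(1:500, function(t) substream_seed(1, "s", t, "x"),
                  integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_equal(length(unique(seeds)), 500)
})
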