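test_that("weaning age starts at 214.5 d and drops 21 d per cycle", {
  expect_equal(weaning_age(1), 214.5)
  expect_equal(weaning_age(2), 193.5)
  expect_equal(weaning_age(6), 109.5)
  expect_equal(diff(weaning_age(1:6)), rep(-21, 5))
  expect_error(weaning_age(0), ">= 1")
})

test_that("weaning weight is birth weight plus gain", {
  expect_equal(weaning_weight(214.5, 80, 2), 509)
  expect_equal(weaning_weight(0, 80, 2), 80)
  expect_equal(weaning_weight(109.5, 80, 2), 299)
  expect_error(weaning_weight(-1), "non-negative")
})

test_that("the price slide uses half-open 50-lb classes", {
  s <- price_slide()
  expect_equal(price_for_weight(509, s), 2.15) # class (500, 550]
  expect_equal(price_for_weight(467, s), 2.23) # class (450, 500]
  expect_equal(price_for_weight(250, s), 2.40)
  expect_equal(price_for_weight(500, s), 2.23) # exact multiple -> lower class
  expect_equal(price_for_weight(550.0000001, s), 2.09)
  # clamping outside the table
  expect_equal(price_for_weight(100, s), 2.40)
  expect_equal(price_for_weight(900, s), 1.84)
  expect_error(price_for_weight(0, s), "positive")
})

test_that("cohorts apply pregnancy and calf survival to conceptions", {
  co <- calf_cohorts(c(660, 224.4), abortion_rate = 0, death_loss = 0)
  expect_equal(co$count, c(660, 224.4))
  expect_equal(co$weight, c(509, 467))
  expect_equal(co$unit_price, c(2.15, 2.23))
  co2 <- calf_cohorts(100, abortion_rate = 0.01, death_loss = 0.01)
  expect_equal(co2$count, 98.01)
})

test_that("annual calf revenue composes counts, weights, and prices", {
  co <- calf_cohorts(c(660, 224.4), abortion_rate = 0.01, death_loss = 0.01)
  # frozen: (660*509*2.15 + 224.4*467*2.23) * 0.9801
  expect_equal(annual_calf_revenue(co), 936939.7322604, tolerance = 1e-9)
  expect_equal(annual_calf_revenue(calf_cohorts(0)), 0)
})

test_that("average weaning weight is the calf-weighted mean", {
  co <- calf_cohorts(c(660, 224.4), abortion_rate = 0, death_loss = 0)
  expect_equal(average_weaning_weight(co), 498.34328358209, tolerance = 1e-9)
  one <- calf_cohorts(50)
  expect_equal(average_weaning_weight(one), one$weight)
  expect_error(average_weaning_weight(calf_cohorts(0)), "zero")
})

test_that("survival rates scale revenue linearly but leave weights alone", {
  ic <- c(400, 180, 70)
  base <- calf_cohorts(ic, abortion_rate = 0, death_loss = 0)
  lossy <- calf_cohorts(ic, abortion_rate = 0.05, death_loss = 0.03)
  expect_equal(average_weaning_weight(lossy), average_weaning_weight(base))
  expect_equal(annual_calf_revenue(lossy),
               annual_calf_revenue(base) * 0.95 * 0.97)
})

test_that("longer seasons wean lighter calf crops at fixed fertility", {
  wt_for_K <- vapply(2:6, function(K) {
    m <- simulate_reproduction(1000, K, 0.66, 50)
    cohorts <- do.call(rbind, lapply(seq_len(nrow(m)), function(t) {
      calf_cohorts(m[t, ], abortion_rate = 0, death_loss = 0)
    }))
    average_weaning_weight(cohorts)
  }, numeric(1))
  expect_true(all(diff(wt_for_K) < 0))
})

test_that("per-year revenue vector matches the per-year cohort computation", {
  m <- simulate_reproduction(1000, 4, 0.6, 10)
  by_year <- calf_revenue_by_year(m, abortion_rate = 0.01, death_loss = 0.01)
  direct <- vapply(seq_len(nrow(m)), function(t) {
    annual_calf_revenue(calf_cohorts(m[t, ], abortion_rate = 0.01,
                                     death_loss = 0.01))
  }, numeric(1))
  expect_equal(by_year, direct)
})
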