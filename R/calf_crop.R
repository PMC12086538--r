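#' Average age at weaning of calves conceived in a given estrus cycle
#'
#' All calves are weaned and sold 225 days after the scheduled start of the
#' calving season. A calf conceived in cycle 1 is born, on average, in the
#' middle of the first 21-day cycle of the calving season (10.5 d in), so its
#' average weaning age is 225 - 10.5 = 214.5 d; each later conception cycle
#' shifts birth, and hence weaning age, 21 days.
#'
#' @param cycle Conception cycle index (1-based); may be a vector.
#' @return Average age at weaning in days.
#' @examples
#' weaning_age(1:6)
#' @export
weaning_age <- function(cycle) {
  if (any(cycle < 1)) stop("cycle index must be >= 1", call. = FALSE)
  225 - 10.5 - 21 * (cycle - 1)
}

#' Average weaning weight from age
#'
#' Linear growth: birth weight plus average daily gain times age.
#'
#' @param age Age at weaning (days).
#' @param birth_weight Average birth weight (lb).
#' @param adg Average daily gain (lb/day).
#' @return Weight in lb.
#' @export
weaning_weight <- function(age, birth_weight = 80, adg = 2.0) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  birth_weight + adg * age
}

#' Price per pound for a calf of given average weight
#'
#' Applies the price slide with half-open 50-lb classes: a weight in
#' `(class_weight, class_weight + 50]` receives the price of that class row,
#' so an exact multiple of 50 lb falls in the class below it (500 lb prices at
#' the 450-lb row). Weights outside the table clamp to the end classes.
#'
#' @param weight Average calf weight (lb); may be a vector.
#' @param slide A [price_slide()] object.
#' @return Price in $/lb.
#' @examples
#' price_for_weight(c(509, 467, 250), price_slide())
#' @export
price_for_weight <- function(weight, slide = price_slide()) {
  if (any(weight <= 0)) stop("weight must be positive", call. = FALSE)
  lo <- 50 * (ceiling(round(weight / 50, 9)) - 1)
  lo <- pmin(pmax(lo, min(slide$class_weight)), max(slide$class_weight))
  slide$price[match(lo, slide$class_weight)]
}

#' Weaned-calf cohorts for one production year
#'
#' Converts the per-cycle conceptions of one year into weaned-calf cohorts:
#' the number of calves weaned from cycle `k` is the conceptions times the
#' fraction of pregnancies not aborted and the fraction of calves that
#' survive to weaning. Each cohort carries its average weaning age, weight,
#' and slide price.
#'
#' @param conceptions Numeric vector of per-cycle conceptions for one year.
#' @param budget A [budget_params()] object (birth weight, daily gain).
#' @param slide A [price_slide()] object.
#' @param abortion_rate Fraction of pregnancies lost after diagnosis.
#' @param death_loss Fraction of calves that die between birth and weaning.
#'
#' @return A data frame with one row per cycle: `cycle`, `count`,
#'   `age_at_weaning`, `weight`, `unit_price`.
#' @export
calf_cohorts <- function(conceptions, budget = budget_params(),
                         slide = price_slide(),
                         abortion_rate = 0.01, death_loss = 0.01) {
  stopifnot(abortion_rate >= 0, abortion_rate < 1,
            death_loss >= 0, death_loss < 1)
  k <- seq_along(conceptions)
  age <- weaning_age(k)
  wt <- weaning_weight(age, budget$calf_birth_weight, budget$calf_adg)
  data.frame(
    cycle = k,
    count = conceptions * (1 - abortion_rate) * (1 - death_loss),
    age_at_weaning = age,
    weight = wt,
    unit_price = price_for_weight(wt, slide)
  )
}

#' Total calf revenue for one production year
#'
#' @param cohorts A [calf_cohorts()] data frame.
#' @return Revenue in dollars: sum over cycles of count x weight x price.
#' @export
annual_calf_revenue <- function(cohorts) {
  stopifnot(nrow(cohorts) >= 1)
  sum(cohorts$count * cohorts$weight * cohorts$unit_price)
}

#' Calf-count-weighted average weaning weight
#'
#' @param cohorts A [calf_cohorts()] data frame (or several years' worth,
#'   row-bound).
#' @return Weight in lb.
#' @export
average_weaning_weight <- function(cohorts) {
  total <- sum(cohorts$count)
  if (total <= 0) stop("no calves weaned: total cohort count is zero",
                       call. = FALSE)
  sum(cohorts$count * cohorts$weight) / total
}

#' Per-year calf revenue over a planning horizon
#'
#' Vectorised composition of [calf_cohorts()] and [annual_calf_revenue()]
#' over every year of a conception matrix.
#'
#' @param conceptions A [simulate_reproduction()] matrix (years x cycles).
#' @inheritParams calf_cohorts
#' @return Numeric vector of annual calf revenue ($), one entry per year.
#' @export
calf_revenue_by_year <- function(conceptions, budget = budget_params(),
                                 slide = price_slide(),
                                 abortion_rate = 0.01, death_loss = 0.01) {
  k <- seq_len(ncol(conceptions))
  wt <- weaning_weight(weaning_age(k), budget$calf_birth_weight,
                       budget$calf_adg)
  value_per_conception <- wt * price_for_weight(wt, slide) *
    (1 - abortion_rate) * (1 - death_loss)
  as.numeric(unclass(conceptions) %*% value_per_conception)
}
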