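#' Salvage revenue from culled animals
#'
#' @param count Animals sold (may be fractional for open-cow culls).
#' @param weight Salvage weight per head (lb).
#' @param price Salvage price ($/lb).
#' @return Revenue in dollars.
#' @examples
#' cull_revenue(1, 1000, 0.86) # one cull cow
#' @export
cull_revenue <- function(count, weight, price) {
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  count * weight * price
}

#' Annual bull maintenance cost
#'
#' Feed, yardage, and veterinary upkeep per bull, plus the evaluation fee for
#' a strategy that screens its bulls. Cow maintenance is identical between
#' strategies and deliberately excluded from the comparison.
#'
#' @param n_bulls Bulls in the battery.
#' @param strategy A [strategy_config()] object.
#' @param budget A [budget_params()] object.
#' @return Cost in dollars.
#' @export
bull_maintenance <- function(n_bulls, strategy, budget = budget_params()) {
  stopifnot(n_bulls >= 0)
  n_bulls * (budget$bull_maintenance_cost +
               if (strategy$uses_bse) budget$bse_fee else 0)
}

#' Replacement purchase costs for one period
#'
#' Every culled or dead animal is replaced in the same period so that herd
#' sizes are restored: culled and dead cows by bred heifers, culled and dead
#' bulls by purchased bulls.
#'
#' @param outcome A [cull_outcome()] list (vector-valued fields allowed).
#' @param budget A [budget_params()] object.
#' @return A list with `cow_cost` and `bull_cost` in dollars.
#' @export
replacement_costs <- function(outcome, budget = budget_params()) {
  cow_events <- outcome$cows_open + outcome$cows_nonreproductive +
    outcome$cow_deaths
  bull_events <- outcome$bulls_injury + outcome$bulls_test_fail +
    outcome$bulls_age + outcome$bull_deaths
  list(cow_cost = cow_events * budget$heifer_purchase_price,
       bull_cost = bull_events * budget$bull_purchase_price)
}

#' Net cashflow for one production period
#'
#' Net of the three revenue streams (weaned calves, cull cows, cull bulls)
#' against replacement purchases and bull maintenance. Cow maintenance costs
#' are equal between strategies and excluded by construction.
#'
#' @param calf_revenue,cull_cow_revenue,cull_bull_revenue Revenues ($).
#' @param cow_replacement_cost,bull_replacement_cost,bull_maintenance_cost
#'   Costs ($).
#' @return A data frame with the six components and their `net`; vector
#'   inputs give one row per element.
#' @export
annual_net_cashflow <- function(calf_revenue = 0,
                                cull_cow_revenue = 0,
                                cull_bull_revenue = 0,
                                cow_replacement_cost = 0,
                                bull_replacement_cost = 0,
                                bull_maintenance_cost = 0) {
  out <- data.frame(calf_revenue = calf_revenue,
                    cull_cow_revenue = cull_cow_revenue,
                    cull_bull_revenue = cull_bull_revenue,
                    cow_replacement_cost = cow_replacement_cost,
                    bull_replacement_cost = bull_replacement_cost,
                    bull_maintenance_cost = bull_maintenance_cost)
  stopifnot(all(vapply(out, is.finite, logical(nrow(out)))))
  out$net <- out$calf_revenue + out$cull_cow_revenue + out$cull_bull_revenue -
    out$cow_replacement_cost - out$bull_replacement_cost -
    out$bull_maintenance_cost
  out
}

# Present-value weights for periods t = 1..horizon.
discount_factors <- function(rate, horizon) {
  stopifnot(rate >= 0, horizon >= 1)
  (1 + rate)^-(seq_len(horizon))
}

#' Net present value of a cashflow series
#'
#' Discounts the cashflow of period `t` by `(1 + i)^-t`, `t = 1..T`: the
#' first production year's net revenue is realised one period after the
#' decision point. With `rate = 0` the NPV is the plain sum.
#'
#' @param cashflows Net cashflow per period ($), `t = 1, 2, ...`.
#' @param rate Discount rate per period (fraction, >= 0).
#' @return A list of class `"npv_result"`: `npv`, `per_period_discounted`,
#'   `horizon`, `discount_rate`.
#' @examples
#' npv(rep(1200, 1), rate = 0.2)$npv # 1000
#' @export
npv <- function(cashflows, rate) {
  stopifnot(length(cashflows) >= 1, all(is.finite(cashflows)))
  disc <- cashflows * discount_factors(rate, length(cashflows))
  structure(list(npv = sum(disc),
                 per_period_discounted = disc,
                 horizon = length(cashflows),
                 discount_rate = rate),
            class = "npv_result")
}

#' @export
print.npv_result <- function(x, ...) {
  cat(sprintf("<npv_result> NPV %.2f over %d periods at %.1f%%\n",
              x$npv, x$horizon, 100 * x$discount_rate))
  invisible(x)
}
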