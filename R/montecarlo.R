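#' Pair of management strategies to compare
#'
#' @param bse,nbse [strategy_config()] objects for the screened and
#'   unscreened strategies.
#' @param cycles Breeding-season length in estrus cycles; defaults to the
#'   simulation settings when the pair is run.
#' @param label Optional scenario label used to derive random substreams.
#' @return A list of class `"strategy_pair"`.
#' @export
strategy_pair <- function(bse, nbse, cycles = NULL, label = "pair") {
  stopifnot(inherits(bse, "strategy_config"),
            inherits(nbse, "strategy_config"))
  structure(list(bse = bse, nbse = nbse, cycles = cycles, label = label),
            class = "strategy_pair")
}

# Coerce a scenario_grid() row (or a strategy_pair) to a strategy_pair,
# inheriting culling/mortality probabilities from the configured strategies.
as_strategy_pair <- function(pair, config) {
  if (inherits(pair, "strategy_pair")) {
    return(pair)
  }
  if (is.data.frame(pair) && nrow(pair) == 1L) {
    tweak <- function(template, fertility, ratio) {
      strategy_config(uses_bse = template$uses_bse,
                      fertility = fertility,
                      cow_bull_ratio = ratio,
                      p_injury_cull = template$p_injury_cull,
                      p_test_fail = template$p_test_fail,
                      p_age_cull = template$p_age_cull,
                      p_cow_nr_cull = template$p_cow_nr_cull,
                      p_cow_mortality = template$p_cow_mortality,
                      p_bull_mortality = template$p_bull_mortality)
    }
    return(strategy_pair(
      bse = tweak(config$bse, pair$f_bse, pair$ratio_bse),
      nbse = tweak(config$nbse, pair$f_nbse, pair$ratio_nbse),
      cycles = pair$cycles,
      label = paste0("scenario", pair$scenario)
    ))
  }
  stop("pair must be a strategy_pair or a single scenario_grid() row",
       call. = FALSE)
}

# Monte Carlo NPVs for one strategy: deterministic reproduction and calf
# revenue shared across iterations; stochastic culls and mortality drawn from
# named substreams per (scenario, strategy, year, event). Iterations are
# vector lanes, so lane i is identical whichever n >= i is requested.
strategy_npv_draws <- function(strategy, config, cycles, n, seed, scenario_key,
                               strategy_key, audit = FALSE) {
  sim <- config$simulation
  budget <- config$budget
  ch <- sim$herd_size
  bh <- bulls_required(ch, strategy$cow_bull_ratio)
  conc <- simulate_reproduction(ch, cycles, strategy$fertility, sim$horizon)
  pregnant <- rowSums(conc)
  open <- ch - pregnant
  calf_rev <- calf_revenue_by_year(conc, budget, config$prices,
                                   sim$abortion_rate, sim$calf_death_loss)
  maint <- bull_maintenance(bh, strategy, budget)
  w <- discount_factors(sim$discount_rate, sim$horizon)
  draw <- function(t, event, trials, prob) {
    set.seed(substream_seed(seed, scenario_key, strategy_key, t, event))
    draw_binomial(trials, prob, n)
  }
  npv_acc <- numeric(n)
  audit_rows <- if (audit) vector("list", sim$horizon) else NULL
  for (t in seq_len(sim$horizon)) {
    injury <- draw(t, "injury", bh, strategy$p_injury_cull)
    test_fail <- if (strategy$uses_bse) {
      draw(t, "test", bh - injury, strategy$p_test_fail)
    } else {
      integer(n)
    }
    age <- draw(t, "age", bh - injury - test_fail, strategy$p_age_cull)
    nr <- draw(t, "nr", round(pregnant[t]), strategy$p_cow_nr_cull)
    cow_deaths <- draw(t, "cow_mortality", ch, strategy$p_cow_mortality)
    bull_deaths <- draw(t, "bull_mortality", bh, strategy$p_bull_mortality)
    outcome <- cull_outcome(bulls_injury = injury, bulls_test_fail = test_fail,
                            bulls_age = age, cows_open = open[t],
                            cows_nonreproductive = nr,
                            cow_deaths = cow_deaths, bull_deaths = bull_deaths)
    repl <- replacement_costs(outcome, budget)
    net <- calf_rev[t] +
      cull_revenue(open[t] + nr, budget$cow_cull_weight,
                   budget$cow_cull_price) +
      cull_revenue(injury + test_fail + age, budget$bull_cull_weight,
                   budget$bull_cull_price) -
      repl$cow_cost - repl$bull_cost - maint
    npv_acc <- npv_acc + net * w[t]
    if (audit) {
      audit_rows[[t]] <- data.frame(year = t, bulls_injury = injury[1],
                                    bulls_test_fail = test_fail[1],
                                    bulls_age = age[1],
                                    cows_open = open[t],
                                    cows_nonreproductive = nr[1],
                                    cow_deaths = cow_deaths[1],
                                    bull_deaths = bull_deaths[1])
    }
  }
  if (audit) {
    attr(npv_acc, "audit") <- do.call(rbind, audit_rows)
  }
  npv_acc
}

#' Run paired Monte Carlo iterations for one scenario
#'
#' Each iteration simulates both strategies over the full planning horizon
#' and records the NPV difference `delta = NPV(BSE) - NPV(NBSE)`. The
#' deterministic reproduction and calf-revenue layers are computed once per
#' strategy; culling and mortality draws come from independent substreams per
#' strategy (or shared substreams when `common_random_numbers = TRUE`, a
#' variance-reduction pairing under which identical strategies give
#' `delta = 0` exactly).
#'
#' @param pair A [strategy_pair()] or a single row of [scenario_grid()].
#' @param config A [herd_config()] object.
#' @param n Number of iterations.
#' @param seed Base seed for the substream hierarchy.
#' @param common_random_numbers Share event substreams between strategies.
#' @return A list of class `"mc_result"`: `iterations` (data frame with
#'   `iteration`, `npv_bse`, `npv_nbse`, `delta`), `p_positive` (fraction of
#'   iterations with `delta > 0`; exact ties count as not positive),
#'   `mean_delta`, `sd_delta`, `n`, `seed`.
#' @export
run_simulation <- function(pair, config = herd_config(),
                           n = config$simulation$iterations,
                           seed = config$simulation$seed,
                           common_random_numbers = FALSE) {
  stopifnot(n >= 1)
  pair <- as_strategy_pair(pair, config)
  cycles <- pair$cycles %||% config$simulation$breeding_cycles
  key_bse <- if (common_random_numbers) "shared" else "bse"
  key_nbse <- if (common_random_numbers) "shared" else "nbse"
  npv_bse <- strategy_npv_draws(pair$bse, config, cycles, n, seed,
                                pair$label, key_bse)
  npv_nbse <- strategy_npv_draws(pair$nbse, config, cycles, n, seed,
                                 pair$label, key_nbse)
  delta <- npv_bse - npv_nbse
  structure(list(
    iterations = data.frame(iteration = seq_len(n), npv_bse = npv_bse,
                            npv_nbse = npv_nbse, delta = delta),
    p_positive = mean(delta > 0),
    mean_delta = mean(delta),
    sd_delta = if (n > 1) stats::sd(delta) else NA_real_,
    n = as.integer(n),
    seed = as.integer(seed)
  ), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> n = %d iterations (seed %d)\n", x$n, x$seed))
  cat(sprintf("  P(dNPV > 0) = %.3f;  mean dNPV = %.0f (sd %.0f)\n",
              x$p_positive, x$mean_delta, x$sd_delta))
  invisible(x)
}

#' Reproduce a single Monte Carlo iteration
#'
#' Iteration `i` occupies lane `i` of the vectorised substreams, so its
#' result is identical whether it is drawn alone or as part of a larger run.
#'
#' @inheritParams run_simulation
#' @param iteration Iteration index to reproduce.
#' @return One row of the `iterations` data frame of [run_simulation()].
#' @export
run_iteration <- function(pair, config = herd_config(), iteration = 1,
                          seed = config$simulation$seed,
                          common_random_numbers = FALSE) {
  res <- run_simulation(pair, config, n = iteration, seed = seed,
                        common_random_numbers = common_random_numbers)
  res$iterations[iteration, , drop = FALSE]
}

#' Monte Carlo sweep over a scenario grid
#'
#' Runs [run_simulation()] for every scenario pair in the grid and collects
#' `P(dNPV > 0)` per (breeding-season length, fertility difference, cow:bull
#' pairing).
#'
#' @param config A [herd_config()] object.
#' @param grid A [scenario_grid()] data frame.
#' @param n Iterations per scenario.
#' @param seed Base seed; each scenario and strategy draws from its own
#'   substream.
#' @param common_random_numbers Share event substreams between strategies.
#' @param verbose Print progress.
#' @return The grid with columns `p_positive`, `mean_delta`, `sd_delta`,
#'   `n`, `seed` appended; class `"sweep_result"`.
#' @export
sweep_scenarios <- function(config = herd_config(), grid = scenario_grid(),
                            n = config$simulation$iterations,
                            seed = config$simulation$seed,
                            common_random_numbers = FALSE,
                            verbose = FALSE) {
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mc <- run_simulation(grid[i, , drop = FALSE], config, n = n, seed = seed,
                         common_random_numbers = common_random_numbers)
    res[[i]] <- data.frame(p_positive = mc$p_positive,
                           mean_delta = mc$mean_delta,
                           sd_delta = mc$sd_delta)
    if (verbose && i %% 10 == 0) {
      message(sprintf("scenario %d / %d", i, nrow(grid)))
    }
  }
  out <- cbind(grid, do.call(rbind, res))
  out$n <- as.integer(n)
  out$seed <- as.integer(seed)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Fertility difference at which the strategies are financially equivalent
#'
#' Locates, by linear interpolation on a cumulative-probability curve, the
#' fertility difference `d` at which `P(dNPV > 0)` first crosses 50%. When
#' the curve starts at or above 50% the indifference point lies below the
#' evaluated grid; when it never reaches 50% it lies above.
#'
#' @param fertility_diff Grid of fertility differences (increasing).
#' @param p_positive `P(dNPV > 0)` at each grid point.
#' @return A list with `status` (`"crossing"`, `"below_grid"`, or
#'   `"above_grid"`) and `value` (the interpolated difference, or `NA`).
#' @examples
#' indifference_point(c(0, 0.01, 0.02), c(0.2, 0.5, 0.9))$value # 0.01
#' @export
indifference_point <- function(fertility_diff, p_positive) {
  stopifnot(length(fertility_diff) == length(p_positive),
            length(fertility_diff) >= 1,
            !is.unsorted(fertility_diff, strictly = TRUE))
  side <- sign(p_positive - 0.5)
  side <- side[side != 0] # touching 50% exactly is not a double crossing
  crossings <- sum(diff(side) != 0)
  if (crossings > 1) {
    warning("curve crosses 50% more than once; reporting the first crossing")
  }
  at_or_above <- which(p_positive >= 0.5)
  if (!length(at_or_above)) {
    return(list(status = "above_grid", value = NA_real_))
  }
  i <- at_or_above[1L]
  if (i == 1L) {
    return(list(status = "below_grid", value = NA_real_))
  }
  frac <- (0.5 - p_positive[i - 1L]) / (p_positive[i] - p_positive[i - 1L])
  list(status = "crossing",
       value = fertility_diff[i - 1L] +
         frac * (fertility_diff[i] - fertility_diff[i - 1L]))
}

#' Indifference points for every curve of a sweep
#'
#' @param sweep A [sweep_scenarios()] result.
#' @return A data frame with one row per (cycles, pairing) curve: `cycles`,
#'   `pairing`, `status`, `indifference_diff`.
#' @export
indifference_table <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  curves <- unique(sweep[, c("cycles", "pairing")])
  rows <- lapply(seq_len(nrow(curves)), function(i) {
    sub <- sweep[sweep$cycles == curves$cycles[i] &
                   sweep$pairing == curves$pairing[i], ]
    sub <- sub[order(sub$fertility_diff), ]
    ip <- indifference_point(sub$fertility_diff, sub$p_positive)
    data.frame(cycles = curves$cycles[i], pairing = curves$pairing[i],
               status = ip$status, indifference_diff = ip$value)
  })
  out <- do.call(rbind, rows)
  out[order(out$pairing, out$cycles), ]
}

#' Per-period culling audit for one iteration
#'
#' Records the first iteration's cull and mortality counts for each strategy
#' and production year, for inspection of the stochastic layer.
#'
#' @inheritParams run_simulation
#' @return A data frame with columns `strategy`, `year`, and the
#'   [cull_outcome()] fields.
#' @export
audit_culls <- function(pair, config = herd_config(),
                        seed = config$simulation$seed) {
  pair <- as_strategy_pair(pair, config)
  cycles <- pair$cycles %||% config$simulation$breeding_cycles
  out <- lapply(c("bse", "nbse"), function(key) {
    draws <- strategy_npv_draws(pair[[key]], config, cycles, n = 1,
                                seed = seed, scenario_key = pair$label,
                                strategy_key = key, audit = TRUE)
    cbind(strategy = toupper(key), attr(draws, "audit"))
  })
  do.call(rbind, out)
}
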