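#' Budget parameters for bulls, cows, and calves
#'
#' Constructs the set of prices, weights, and biological constants that drive
#' the capital budget. Defaults are the baseline values for a southeastern
#' U.S. cow-calf operation: Brangus-type bull purchase prices, slaughter
#' cow/bull salvage values, and bred-heifer replacement prices.
#'
#' @param bull_maintenance_cost Annual cost to maintain one bull ($/bull/yr).
#' @param bse_fee Annual veterinary fee per bull for a breeding soundness
#'   evaluation ($/bull/yr); charged only under the BSE strategy.
#' @param bull_purchase_price Replacement bull purchase price ($/head).
#' @param bull_cull_weight Salvage weight of a cull bull (lb).
#' @param bull_cull_price Salvage price for cull bulls ($/lb).
#' @param bull_lifespan Average working life span of a bull (yr); its inverse
#'   is the default annual age-cull probability.
#' @param heifer_purchase_price Price of a bred replacement heifer ($/head).
#' @param cow_cull_weight Salvage weight of a cull cow (lb).
#' @param cow_cull_price Salvage price for cull cows ($/lb).
#' @param cow_lifespan Average working life span of a cow (yr); its inverse is
#'   the default annual non-reproductive cull probability.
#' @param calf_birth_weight Average calf birth weight (lb).
#' @param calf_adg Average daily gain of a nursing calf (lb/day).
#'
#' @return A list of class `"budget_params"`.
#' @examples
#' budget_params()$bull_maintenance_cost
#' @export
budget_params <- function(bull_maintenance_cost = 542.30,
                          bse_fee = 100,
                          bull_purchase_price = 7250,
                          bull_cull_weight = 2000,
                          bull_cull_price = 0.85,
                          bull_lifespan = 4,
                          heifer_purchase_price = 1116,
                          cow_cull_weight = 1000,
                          cow_cull_price = 0.86,
                          cow_lifespan = 10,
                          calf_birth_weight = 80,
                          calf_adg = 2.0) {
  params <- list(
    bull_maintenance_cost = bull_maintenance_cost,
    bse_fee = bse_fee,
    bull_purchase_price = bull_purchase_price,
    bull_cull_weight = bull_cull_weight,
    bull_cull_price = bull_cull_price,
    bull_lifespan = bull_lifespan,
    heifer_purchase_price = heifer_purchase_price,
    cow_cull_weight = cow_cull_weight,
    cow_cull_price = cow_cull_price,
    cow_lifespan = cow_lifespan,
    calf_birth_weight = calf_birth_weight,
    calf_adg = calf_adg
  )
  for (nm in names(params)) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("budget parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (params$bull_lifespan < 1 || params$cow_lifespan < 1) {
    stop("lifespans must be at least 1 year", call. = FALSE)
  }
  structure(params, class = "budget_params")
}

#' Feeder-calf price slide
#'
#' The price slide maps the average weight of a calf cohort to a sale price
#' per pound: price per unit weight decreases as weight-class increases.
#' Defaults are 50-lb weight classes from 250 to 700 lb. A cohort whose
#' average weight falls in the half-open interval
#' `(class_weight, class_weight + 50]` receives that class's price, so an
#' exact multiple of 50 lb prices in the class below it; weights outside the
#' table clamp to the end classes.
#'
#' @param class_weight Strictly increasing lower bounds of the 50-lb weight
#'   classes (lb).
#' @param price Sale price for each class ($/lb).
#'
#' @return A data frame of class `"price_slide"` with columns `class_weight`
#'   and `price`.
#' @seealso [price_for_weight()]
#' @export
price_slide <- function(class_weight = seq(250, 700, by = 50),
                        price = c(2.40, 2.41, 2.37, 2.30, 2.23,
                                  2.15, 2.09, 2.01, 1.94, 1.84)) {
  if (length(class_weight) != length(price) || length(price) < 1L) {
    stop("class_weight and price must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(class_weight)) || any(!is.finite(price)) ||
      any(price <= 0)) {
    stop("price slide entries must be finite and prices positive",
         call. = FALSE)
  }
  steps <- diff(class_weight)
  if (length(steps) && (any(steps <= 0) || any(steps != 50))) {
    stop("price slide class weights must increase in steps of 50 lb",
         call. = FALSE)
  }
  structure(
    data.frame(class_weight = as.numeric(class_weight),
               price = as.numeric(price)),
    class = c("price_slide", "data.frame")
  )
}

#' Bull-management strategy settings
#'
#' Bundles the fertility and culling parameters of one management strategy.
#' The defaults differ by strategy: screening bulls (BSE) is assumed to roughly
#' double the chance of an injury/temperament/size cull (1 in 10 vs. 1 in 20)
#' because of the extra handling, and adds a 20% chance that a presented bull
#' fails the evaluation and is culled. Age culls occur at the inverse of the
#' bull's working life span under either strategy.
#'
#' @param uses_bse Logical; does this strategy screen bulls with a breeding
#'   soundness evaluation?
#' @param fertility Per-cycle incidence rate of conception attributable to the
#'   bull battery, in (0, 1]. Bull fertility is the rate-limiting factor, so
#'   this is also the herd-level per-cycle conception probability for eligible
#'   cows.
#' @param cow_bull_ratio Cows assigned per bull (e.g. 25 or 33).
#' @param p_injury_cull Annual probability a bull is culled for injury,
#'   temperament, or size.
#' @param p_test_fail Probability a bull presented for evaluation is classed
#'   unsatisfactory and culled. Ignored (forced to 0) when `uses_bse` is
#'   `FALSE`.
#' @param p_age_cull Annual probability a bull is culled for age; defaults to
#'   1 / bull working life span.
#' @param p_cow_nr_cull Annual probability a pregnant cow is culled for
#'   non-reproductive reasons; defaults to 1 / cow working life span.
#' @param p_cow_mortality,p_bull_mortality Annual mortality probabilities.
#'
#' @return A list of class `"strategy_config"`.
#' @export
strategy_config <- function(uses_bse,
                            fertility = 0.66,
                            cow_bull_ratio = 25,
                            p_injury_cull = if (uses_bse) 0.10 else 0.05,
                            p_test_fail = if (uses_bse) 0.20 else 0,
                            p_age_cull = 0.25,
                            p_cow_nr_cull = 0.10,
                            p_cow_mortality = 0.01,
                            p_bull_mortality = 0.01) {
  if (!is.logical(uses_bse) || length(uses_bse) != 1L || is.na(uses_bse)) {
    stop("uses_bse must be TRUE or FALSE", call. = FALSE)
  }
  if (!is.numeric(fertility) || length(fertility) != 1L ||
      fertility <= 0 || fertility > 1) {
    stop("fertility must be a probability in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(cow_bull_ratio) || length(cow_bull_ratio) != 1L ||
      cow_bull_ratio < 1) {
    stop("cow_bull_ratio must be at least 1", call. = FALSE)
  }
  probs <- list(p_injury_cull = p_injury_cull, p_test_fail = p_test_fail,
                p_age_cull = p_age_cull, p_cow_nr_cull = p_cow_nr_cull,
                p_cow_mortality = p_cow_mortality,
                p_bull_mortality = p_bull_mortality)
  for (nm in names(probs)) {
    v <- probs[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("'", nm, "' must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (!uses_bse) p_test_fail <- 0
  structure(
    list(uses_bse = uses_bse,
         fertility = fertility,
         cow_bull_ratio = cow_bull_ratio,
         p_injury_cull = p_injury_cull,
         p_test_fail = p_test_fail,
         p_age_cull = p_age_cull,
         p_cow_nr_cull = p_cow_nr_cull,
         p_cow_mortality = p_cow_mortality,
         p_bull_mortality = p_bull_mortality),
    class = "strategy_config"
  )
}

#' Simulation settings
#'
#' Herd size, planning horizon, discounting, calf-loss rates, and Monte Carlo
#' controls. The 1,000-cow herd acts as a scalar that yields whole-number bull
#' batteries; the 50-year horizon approximates a producer's maximum working
#' life; the 20% discount rate reflects the high cost of capital observed for
#' cow-calf enterprises.
#'
#' @param herd_size Number of mature cows maintained each period.
#' @param horizon Number of annual production periods to simulate.
#' @param discount_rate Annual discount rate used for NPV (fraction).
#' @param breeding_cycles Breeding-season length in 21-day estrus cycles.
#' @param abortion_rate Fraction of diagnosed pregnancies lost before calving.
#' @param calf_death_loss Fraction of calves born that die before weaning.
#' @param iterations Monte Carlo iterations per scenario.
#' @param seed Integer seed from which all random substreams are derived.
#'
#' @return A list of class `"sim_settings"`.
#' @export
sim_settings <- function(herd_size = 1000,
                         horizon = 50,
                         discount_rate = 0.20,
                         breeding_cycles = 3,
                         abortion_rate = 0.01,
                         calf_death_loss = 0.01,
                         iterations = 500,
                         seed = 1L) {
  if (!is.numeric(herd_size) || herd_size < 1) {
    stop("herd_size must be at least 1", call. = FALSE)
  }
  if (!is.numeric(horizon) || horizon < 1) {
    stop("horizon must be at least 1 period", call. = FALSE)
  }
  if (!is.numeric(breeding_cycles) || breeding_cycles < 1) {
    stop("breeding_cycles must be at least 1", call. = FALSE)
  }
  if (!is.numeric(discount_rate) || discount_rate < 0) {
    stop("discount_rate must be non-negative", call. = FALSE)
  }
  for (nm in c("abortion_rate", "calf_death_loss")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v >= 1) {
      stop("'", nm, "' must be in [0, 1)", call. = FALSE)
    }
  }
  if (!is.numeric(iterations) || iterations < 1) {
    stop("iterations must be at least 1", call. = FALSE)
  }
  structure(
    list(herd_size = as.integer(herd_size),
         horizon = as.integer(horizon),
         discount_rate = discount_rate,
         breeding_cycles = as.integer(breeding_cycles),
         abortion_rate = abortion_rate,
         calf_death_loss = calf_death_loss,
         iterations = as.integer(iterations),
         seed = as.integer(seed)),
    class = "sim_settings"
  )
}

#' Assemble a full model configuration
#'
#' @param budget A [budget_params()] object.
#' @param prices A [price_slide()] object.
#' @param bse,nbse [strategy_config()] objects for the screened and unscreened
#'   strategies.
#' @param simulation A [sim_settings()] object.
#'
#' @return A list of class `"herd_config"`.
#' @export
herd_config <- function(budget = budget_params(),
                        prices = price_slide(),
                        bse = strategy_config(uses_bse = TRUE),
                        nbse = strategy_config(uses_bse = FALSE),
                        simulation = sim_settings()) {
  stopifnot(inherits(budget, "budget_params"),
            inherits(prices, "price_slide"),
            inherits(bse, "strategy_config"),
            inherits(nbse, "strategy_config"),
            inherits(simulation, "sim_settings"))
  structure(list(budget = budget, prices = prices, bse = bse, nbse = nbse,
                 simulation = simulation),
            class = "herd_config")
}

#' @export
print.herd_config <- function(x, ...) {
  s <- x$simulation
  cat("<herd_config>\n")
  cat(sprintf("  herd: %d cows, %d-yr horizon, discount %.0f%%\n",
              s$herd_size, s$horizon, 100 * s$discount_rate))
  cat(sprintf("  season: %d estrus cycles; calf survival %.4f\n",
              s$breeding_cycles,
              (1 - s$abortion_rate) * (1 - s$calf_death_loss)))
  cat(sprintf("  BSE : fertility %.2f, %g:1 cows per bull\n",
              x$bse$fertility, x$bse$cow_bull_ratio))
  cat(sprintf("  NBSE: fertility %.2f, %g:1 cows per bull\n",
              x$nbse$fertility, x$nbse$cow_bull_ratio))
  invisible(x)
}

#' Load a model configuration from a YAML file
#'
#' Reads a configuration with optional sections `budget`, `prices`, `bse`,
#' `nbse`, and `simulation`. Fields omitted from the file keep their package
#' defaults; unknown fields are an error. An empty file yields the default
#' configuration.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated [herd_config()] object.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("budget", "prices", "bse", "nbse", "simulation")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  call_with <- function(fun, args, where) {
    ok <- names(formals(fun))
    bad <- setdiff(names(args), ok)
    if (length(bad)) {
      stop("unknown field(s) in [", where, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    do.call(fun, args)
  }
  budget <- call_with(budget_params, raw$budget %||% list(), "budget")
  prices <- call_with(price_slide, raw$prices %||% list(), "prices")
  bse <- call_with(strategy_config,
                   c(list(uses_bse = TRUE), raw$bse %||% list()), "bse")
  nbse <- call_with(strategy_config,
                    c(list(uses_bse = FALSE), raw$nbse %||% list()), "nbse")
  simulation <- call_with(sim_settings, raw$simulation %||% list(),
                          "simulation")
  herd_config(budget, prices, bse, nbse, simulation)
}

#' Write a model configuration to a YAML file
#'
#' The written file round-trips: `load_config(write_config(cfg, path))`
#' reproduces `cfg` exactly.
#'
#' @param config A [herd_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "herd_config"))
  out <- list(
    budget = unclass(config$budget),
    prices = list(class_weight = config$prices$class_weight,
                  price = config$prices$price),
    bse = unclass(config$bse)[setdiff(names(config$bse), "uses_bse")],
    nbse = unclass(config$nbse)[setdiff(names(config$nbse), "uses_bse")],
    simulation = unclass(config$simulation)
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of bulls required for a herd
#'
#' The bull battery is the herd size divided by the cow:bull ratio, rounded to
#' the nearest whole bull (e.g. 1000 cows at 33:1 run 30 bulls, matching the
#' "3 bulls per 100 cows" convention).
#'
#' @param herd_size Number of cows.
#' @param ratio Cows per bull.
#' @return Integer number of bulls (at least 1).
#' @examples
#' bulls_required(1000, 25) # 40
#' bulls_required(1000, 33) # 30
#' @export
bulls_required <- function(herd_size, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0) {
    stop("ratio must be a positive number", call. = FALSE)
  }
  if (!is.numeric(herd_size) || length(herd_size) != 1L ||
      herd_size < ratio || ratio < 1) {
    stop("need herd_size >= ratio >= 1", call. = FALSE)
  }
  max(1L, as.integer(round(herd_size / ratio)))
}

#' Factorial grid of paired management scenarios
#'
#' Builds the full factorial of breeding-season length, fertility difference,
#' and cow:bull pairing over which the Monte Carlo comparison runs. The BSE
#' strategy's fertility is held at the biological maximum (`f_bse`, default
#' 66%); the NBSE strategy's fertility is `f_bse - d` for each difference `d`.
#' The default pairings run both strategies at 25:1, and the BSE strategy at
#' 33:1 against NBSE at 25:1.
#'
#' @param cycles Breeding-season lengths to evaluate (estrus cycles).
#' @param fertility_diff Absolute per-cycle fertility differences `d`.
#' @param pairings List of two-element vectors `c(ratio_bse, ratio_nbse)`.
#' @param f_bse Per-cycle conception probability under the BSE strategy.
#'
#' @return A data frame with one row per scenario pair: columns `scenario`,
#'   `cycles`, `fertility_diff`, `ratio_bse`, `ratio_nbse`, `pairing`,
#'   `f_bse`, `f_nbse`.
#' @examples
#' nrow(scenario_grid()) # 130
#' @export
scenario_grid <- function(cycles = 2:6,
                          fertility_diff = seq(0, 0.12, by = 0.01),
                          pairings = list(c(25, 25), c(33, 25)),
                          f_bse = 0.66) {
  stopifnot(all(fertility_diff >= 0), all(fertility_diff < f_bse))
  rows <- expand.grid(pairing_idx = seq_along(pairings),
                      fertility_diff = fertility_diff,
                      cycles = as.integer(cycles),
                      KEEP.OUT.ATTRS = FALSE)
  ratio_bse <- vapply(pairings, `[`, numeric(1), 1L)[rows$pairing_idx]
  ratio_nbse <- vapply(pairings, `[`, numeric(1), 2L)[rows$pairing_idx]
  out <- data.frame(
    scenario = seq_len(nrow(rows)),
    cycles = rows$cycles,
    fertility_diff = rows$fertility_diff,
    ratio_bse = ratio_bse,
    ratio_nbse = ratio_nbse,
    pairing = paste0(ratio_bse, ":", ratio_nbse),
    f_bse = f_bse,
    f_nbse = f_bse - rows$fertility_diff
  )
  out <- out[order(out$cycles, out$pairing, out$fertility_diff), ]
  out$scenario <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
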