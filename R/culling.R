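#' Derive an integer seed for a named random substream
#'
#' Hashes a base seed together with an arbitrary sequence of keys (scenario
#' ids, strategy labels, years, event names) into an integer below 2^31,
#' suitable for `set.seed()`. Distinct key sequences give effectively
#' independent substreams; the same keys always give the same stream, so
#' iteration `i` of a simulation is reproducible regardless of how many
#' iterations are run alongside it.
#'
#' @param seed Base integer seed.
#' @param ... Keys identifying the substream; coerced to character.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  keys <- unlist(lapply(list(...), as.character), use.names = FALSE)
  for (key in keys) {
    for (b in utf8ToInt(key)) {
      h <- (h * 69069 + b + 1) %% m
    }
    h <- (h * 69069 + 257) %% m # separator so c("ab","c") != c("a","bc")
  }
  as.integer(h)
}

#' Binomial culling/mortality draw
#'
#' Thin validated wrapper around the binomial sampler used for every
#' stochastic culling and mortality event: each of `trials` animals is
#' independently selected with probability `prob`.
#'
#' @param trials Number of eligible animals (non-negative integer; may be a
#'   vector, recycled against `n`).
#' @param prob Per-animal event probability in `[0, 1]`.
#' @param n Number of independent draws.
#' @return Integer vector of length `n`, each entry in `[0, trials]`.
#' @export
draw_binomial <- function(trials, prob, n = 1) {
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob > 1)) {
    stop("prob must be in [0, 1]", call. = FALSE)
  }
  if (any(trials < 0) || any(trials != floor(trials))) {
    stop("trials must be a non-negative integer", call. = FALSE)
  }
  stats::rbinom(n, size = trials, prob = prob)
}

#' Sequential bull-culling cascade
#'
#' Bulls are culled in a fixed order of events, and only bulls not culled by
#' an earlier event are eligible for the next: first injury/temperament/size,
#' then (BSE strategy only) failing the breeding soundness evaluation, then
#' age. Each event is a binomial draw from the bulls remaining.
#'
#' @param n_bulls Bulls in the battery at the start of the period.
#' @param strategy A [strategy_config()] object.
#' @param n Number of independent replicate periods to draw.
#' @return A data frame with `n` rows and integer columns `injury`,
#'   `test_fail` (all zero for an unscreened strategy), and `age`.
#' @seealso [expected_bull_culls()] for the closed-form moments.
#' @export
bull_cull_cascade <- function(n_bulls, strategy, n = 1) {
  stopifnot(n_bulls >= 0, inherits(strategy, "strategy_config"))
  injury <- draw_binomial(n_bulls, strategy$p_injury_cull, n)
  if (strategy$uses_bse) {
    test_fail <- draw_binomial(n_bulls - injury, strategy$p_test_fail, n)
  } else {
    test_fail <- integer(n)
  }
  age <- draw_binomial(n_bulls - injury - test_fail, strategy$p_age_cull, n)
  data.frame(injury = injury, test_fail = test_fail, age = age)
}

#' Closed-form moments of total bulls culled per period
#'
#' The cascade mean is exact by iterated expectation and matches the
#' stage-by-stage formula `BH p(I) + BH' p(Test) + BH'' p(Age)` with `BH'`,
#' `BH''` the expected survivors of each prior event. Because every bull
#' independently runs the whole cascade, the total culled is exactly
#' `Binomial(BH, 1 - q)` with `q` the product of the per-event survival
#' probabilities, so the exact variance is `BH (1 - q) q`. The stage-plug-in
#' variance `sum n_e p_e (1 - p_e)` — which treats the number eligible at
#' each stage as fixed at its expectation — is also returned, for comparison;
#' it overstates the true spread.
#'
#' @inheritParams bull_cull_cascade
#' @return A list with `mean`, `variance` (exact), and `variance_stagewise`
#'   (stage-plug-in approximation).
#' @examples
#' expected_bull_culls(40, strategy_config(uses_bse = TRUE))$mean  # 18.4
#' expected_bull_culls(40, strategy_config(uses_bse = FALSE))$mean # 11.5
#' @export
expected_bull_culls <- function(n_bulls, strategy) {
  stopifnot(n_bulls >= 0, inherits(strategy, "strategy_config"))
  p <- c(strategy$p_injury_cull,
         if (strategy$uses_bse) strategy$p_test_fail else 0,
         strategy$p_age_cull)
  q <- prod(1 - p)
  eligible <- n_bulls * cumprod(c(1, 1 - p))[seq_along(p)]
  list(
    mean = n_bulls * (1 - q),
    variance = n_bulls * (1 - q) * q,
    variance_stagewise = sum(eligible * p * (1 - p))
  )
}

#' Cow culls for one period
#'
#' Cows diagnosed non-pregnant after the breeding season are all sold: the
#' open-cow cull is the deterministic complement of the expected conceptions
#' and may be fractional. Of the pregnant cows, each is independently culled
#' for non-reproductive reasons (udder conformation, temperament, and so on)
#' with probability `p_nr`; only pregnant cows are eligible for that draw.
#'
#' @param herd_size Number of cows.
#' @param pregnant Cows diagnosed pregnant (possibly fractional).
#' @param p_nr Annual non-reproductive cull probability.
#' @param n Number of independent replicate draws.
#' @return A list with `open` (scalar, fractional) and `nonreproductive`
#'   (integer vector of length `n`).
#' @export
cow_culls <- function(herd_size, pregnant, p_nr, n = 1) {
  stopifnot(pregnant >= 0, pregnant <= herd_size)
  list(
    open = herd_size - pregnant,
    nonreproductive = draw_binomial(round(pregnant), p_nr, n)
  )
}

#' Mortality draws for one period
#'
#' All cows and bulls are eligible for mortality; deaths are replaced
#' immediately (generating replacement cost) but produce no salvage revenue
#' and do not feed the culling cascade.
#'
#' @param herd_size Number of cows.
#' @param n_bulls Number of bulls.
#' @param strategy A [strategy_config()] object (mortality probabilities).
#' @param n Number of independent replicate draws.
#' @return A list of integer vectors `cow_deaths` and `bull_deaths`.
#' @export
mortality_draws <- function(herd_size, n_bulls, strategy, n = 1) {
  stopifnot(inherits(strategy, "strategy_config"))
  list(
    cow_deaths = draw_binomial(herd_size, strategy$p_cow_mortality, n),
    bull_deaths = draw_binomial(n_bulls, strategy$p_bull_mortality, n)
  )
}

#' Cull and mortality outcome for one period
#'
#' Plain container pairing the bull cascade, cow culls, and mortality counts
#' that feed the period's revenue and replacement-cost calculations.
#'
#' @param bulls_injury,bulls_test_fail,bulls_age Integer bull-cull counts.
#' @param cows_open Open-cow cull (fractional, deterministic).
#' @param cows_nonreproductive Integer non-reproductive cow culls.
#' @param cow_deaths,bull_deaths Integer mortality counts.
#' @return A list of class `"cull_outcome"`.
#' @export
cull_outcome <- function(bulls_injury = 0, bulls_test_fail = 0, bulls_age = 0,
                         cows_open = 0, cows_nonreproductive = 0,
                         cow_deaths = 0, bull_deaths = 0) {
  structure(list(bulls_injury = bulls_injury,
                 bulls_test_fail = bulls_test_fail,
                 bulls_age = bulls_age,
                 cows_open = cows_open,
                 cows_nonreproductive = cows_nonreproductive,
                 cow_deaths = cow_deaths,
                 bull_deaths = bull_deaths),
            class = "cull_outcome")
}
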