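#' Eligibility of cows to conceive, lagged by postpartum anestrus
#'
#' A cow that conceives late in one breeding season calves late the next
#' spring and has not completed her postpartum anestrus (about 2.5 estrus
#' cycles) by the time the next season opens. The rule used here: for cycle
#' `k` of the current year, cows bred in cycles up to `k + 1` of the previous
#' year are fully eligible, half of the cows bred in cycle `k + 2` are
#' eligible, and cows bred in any later cycle are ineligible.
#'
#' @param prev_year Numeric vector of per-cycle conceptions in the previous
#'   year (length `K`).
#' @param k Cycle index within the current breeding season (1-based).
#' @param herd_size Number of cows in the herd.
#'
#' @return The fraction of the herd eligible to conceive in cycle `k`,
#'   in `[0, 1]`. Equals 1 whenever `k + 2` exceeds the season length.
#' @examples
#' lagged_eligibility(c(660, 224.4, 76.296), k = 1, herd_size = 1000)
#' @export
lagged_eligibility <- function(prev_year, k, herd_size) {
  K <- length(prev_year)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > K) {
    stop("cycle index k must lie in 1..", K, call. = FALSE)
  }
  if (k + 2 > K) {
    return(1)
  }
  late <- sum(prev_year[(k + 2):K])
  base <- (herd_size - late) / herd_size
  if (base < 1) {
    min(1, base + prev_year[k + 2] / (2 * herd_size))
  } else {
    1
  }
}

#' Per-cycle eligibility vector for one breeding season
#'
#' @inheritParams lagged_eligibility
#' @return Numeric vector of length `K` with entries in `[0, 1]`.
#' @export
eligibility_vector <- function(prev_year, herd_size) {
  vapply(seq_along(prev_year), lagged_eligibility,
         numeric(1), prev_year = prev_year, herd_size = herd_size)
}

#' Cows conceiving in each estrus cycle of one breeding season
#'
#' Sequential expected-value statement: in cycle `k`, the cows not yet
#' impregnated this season conceive with probability `eligibility[k] *
#' fertility`. Bull fertility is the rate-limiting factor, so the per-cycle
#' incidence rate of conception equals bull percentage fertility for eligible
#' cows.
#'
#' @param herd_size Number of cows.
#' @param fertility Per-cycle conception probability in (0, 1].
#' @param eligibility Per-cycle eligibility fractions (length `K`).
#'
#' @return Numeric vector of expected conceptions per cycle; its sum never
#'   exceeds `herd_size`.
#' @examples
#' conceptions_for_year(1000, 0.66, c(1, 1)) # 660, 224.4
#' @export
conceptions_for_year <- function(herd_size, fertility, eligibility) {
  stopifnot(fertility > 0, fertility <= 1,
            all(eligibility >= 0), all(eligibility <= 1))
  K <- length(eligibility)
  ic <- numeric(K)
  bred <- 0
  for (k in seq_len(K)) {
    ic[k] <- (herd_size - bred) * eligibility[k] * fertility
    bred <- bred + ic[k]
  }
  ic
}

#' Deterministic herd-reproduction recursion over the planning horizon
#'
#' Year 1 assumes 100% eligibility in every cycle; each later year's
#' eligibility derives from the previous year's per-cycle conceptions through
#' the postpartum-anestrus lag ([lagged_eligibility()]). Replacement females
#' are purchased as heifers bred to calve within the first two cycles of the
#' calving season, so they are fully eligible and the recursion tracks only
#' the per-cycle conception totals. Conceptions are continuous expected
#' values, not integer draws.
#'
#' @param herd_size Number of cows held constant each period.
#' @param cycles Breeding-season length in estrus cycles (`K`).
#' @param fertility Per-cycle conception probability in (0, 1].
#' @param horizon Number of years to simulate.
#'
#' @return A `horizon` x `cycles` matrix of class `"conception_matrix"`;
#'   entry `[t, k]` is the expected number of cows impregnated in cycle `k`
#'   of year `t`. Attributes `herd_size` and `fertility` record the inputs.
#' @examples
#' m <- simulate_reproduction(1000, cycles = 2, fertility = 0.66, horizon = 5)
#' rowSums(m) # identical every year for a 2-cycle season
#' @export
simulate_reproduction <- function(herd_size, cycles, fertility, horizon) {
  stopifnot(horizon >= 1, cycles >= 1)
  cycles <- as.integer(cycles)
  horizon <- as.integer(horizon)
  ic <- matrix(0, nrow = horizon, ncol = cycles,
               dimnames = list(year = seq_len(horizon),
                               cycle = seq_len(cycles)))
  elig <- rep(1, cycles)
  for (t in seq_len(horizon)) {
    if (t > 1L) elig <- eligibility_vector(ic[t - 1L, ], herd_size)
    ic[t, ] <- conceptions_for_year(herd_size, fertility, elig)
  }
  structure(ic, class = c("conception_matrix", "matrix", "array"),
            herd_size = herd_size, fertility = fertility)
}

#' @export
print.conception_matrix <- function(x, ...) {
  cat(sprintf("<conception_matrix> %d yr x %d cycles (herd %g, fertility %.2f)\n",
              nrow(x), ncol(x), attr(x, "herd_size"), attr(x, "fertility")))
  cat(sprintf("  mean cows bred/yr: %.1f\n", average_cows_bred(x)))
  invisible(x)
}

#' Average annual number of cows bred
#'
#' Arithmetic mean over years of the annual conception totals.
#'
#' @param conceptions A [simulate_reproduction()] matrix (years x cycles).
#' @return Cows per year (fractional).
#' @export
average_cows_bred <- function(conceptions) {
  stopifnot(is.matrix(conceptions), nrow(conceptions) >= 1)
  mean(rowSums(conceptions))
}

#' Write a conception matrix to CSV
#'
#' Rows are years, columns are estrus cycles.
#'
#' @param conceptions A [simulate_reproduction()] matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conception_matrix <- function(conceptions, path) {
  df <- data.frame(year = seq_len(nrow(conceptions)), unclass(conceptions))
  names(df) <- c("year", paste0("cycle_", seq_len(ncol(conceptions))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
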