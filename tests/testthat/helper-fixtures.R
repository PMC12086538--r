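# Shared fixtures for the suite.

default_config <- herd_config()

# A scenario pair built from grid coordinates with the default strategies.
grid_pair <- function(cycles, d, ratio_bse = 25, ratio_nbse = 25,
                      f_bse = 0.66) {
  g <- scenario_grid(cycles = cycles, fertility_diff = d,
                     pairings = list(c(ratio_bse, ratio_nbse)),
                     f_bse = f_bse)
  g[1, , drop = FALSE]
}

# A "null" pair: two copies of the unscreened strategy, so the only source of
# dNPV variation is the independent random streams.
null_pair <- function(fertility = 0.66, ratio = 25) {
  s <- strategy_config(uses_bse = FALSE, fertility = fertility,
                       cow_bull_ratio = ratio)
  strategy_pair(bse = s, nbse = s, label = "null")
}

# Strategy with every stochastic event switched off.
deterministic_strategy <- function(uses_bse, fertility, ratio = 25) {
  strategy_config(uses_bse = uses_bse, fertility = fertility,
                  cow_bull_ratio = ratio,
                  p_injury_cull = 0, p_test_fail = 0, p_age_cull = 0,
                  p_cow_nr_cull = 0, p_cow_mortality = 0,
                  p_bull_mortality = 0)
}
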