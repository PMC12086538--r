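---
title: "A capital-budgeting model of bull breeding soundness evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A capital-budgeting model of bull breeding soundness evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdsim)
```

## The decision problem

A breeding soundness evaluation (BSE) is a veterinary screening exam that
identifies subfertile bulls so they can be culled and replaced. Screening
costs money twice over — the exam fee and the extra bull replacements it
triggers — and pays off only through reproductive efficiency: more cows
pregnant, earlier in the breeding season, weaning heavier calves. `herdsim`
models a 1,000-cow southeastern U.S. cow-calf operation under two bull-battery
policies, **BSE** (screen annually, cull failures) and **NBSE** (do not
screen), and compares them with the decision statistic

$$\Delta NPV = NPV_{BSE} - NPV_{NBSE},$$

the difference in net present value of the two strategies' 50-year cashflow
streams. Because culling and mortality are stochastic, the comparison is a
Monte Carlo estimate of $P(\Delta NPV > 0)$ — the probability that screening
is the more profitable policy — swept across breeding-season lengths,
fertility differences, and cow:bull ratios.

## Model structure

### Herd reproduction

The herd of $CH$ cows is bred over a season of $K$ 21-day estrus cycles. Bull
fertility is treated as the rate-limiting factor, so an eligible cow conceives
in one cycle with probability $f$, the bull battery's per-cycle incidence rate
of conception. Conceptions in cycle $k$ of year $t$ follow the sequential
expected-value statement

$$IC_{k,t} = \Big(CH - \sum_{j<k} IC_{j,t}\Big)\, e_{k,t}\, f,$$

where $e_{k,t}$ is the fraction of the herd eligible to be bred in that cycle.
Eligibility is 100% in every cycle of year 1. Afterwards it encodes a
postpartum anestrus of about 2.5 cycles: a cow bred late in one season calves
late the next spring and is not cycling again when the next season opens. For
cycle $k$, cows bred in cycles up to $k+1$ of the previous year are fully
eligible, *half* of the cows bred in cycle $k+2$ are eligible, and cows bred
later are ineligible:

$$e_{k,t} = \min\!\Big(1,\; \frac{CH - \sum_{j \ge k+2} IC_{j,t-1}}{CH}
  + \frac{IC_{k+2,t-1}}{2\,CH}\Big).$$

Open cows are sold after pregnancy diagnosis and replaced by purchased
heifers bred to calve within the first 42 days of the calving season, so
replacements are fully eligible and the recursion needs only the per-cycle
totals. Conceptions are *continuous expected values*: the deterministic layer
propagates fractional cows rather than sampling them, which is what makes the
long-run averages stable and reproducible. For $K = 2$ the eligibility rule
never binds and the recursion is at a fixed point from year 1.

### Calf crop and the price slide

All calves are weaned and sold 225 days after the scheduled start of the
calving season. A calf conceived in cycle $k$ is born, on average, in the
middle of calving cycle $k$, so its weaning age is $214.5 - 21(k-1)$ days and
its weight is $b + ADG \cdot age$ (80 lb birth weight, 2 lb/day gain: 509 lb
from cycle 1 down to 299 lb from cycle 6). The number weaned from cycle $k$
is $IC_{k,t}\,\alpha\,\delta$, where $\alpha$ is the fraction of diagnosed
pregnancies not aborted and $\delta$ the fraction of calves that survive to
weaning. Revenue prices each cohort through a feeder-calf price slide with
50-lb classes from 250 to 700 lb: a cohort averaging $(w_0, w_0 + 50]$ lb
sells at the $w_0$-row price, so price per pound falls as calves get heavier.
Exact multiples of 50 lb fall in the class below; weights outside the table
clamp to the end classes (never reached at the default parameters, which span
299–509 lb).

### Stochastic culling and mortality

Culling is sequential — no animal can be culled twice in a period:

1. **Bulls, injury/temperament/size:** $\mathrm{Bin}(BH, p_I)$, with
   $p_I = 0.10$ under BSE (gathering and processing bulls is itself risky)
   and $0.05$ under NBSE.
2. **Bulls, failed evaluation (BSE only):** $\mathrm{Bin}(BH - I, 0.20)$.
3. **Bulls, age:** binomial on the remaining bulls with $p = 1/4$, the
   inverse of a 4-year working life.
4. **Cows, open:** deterministic, $CH - \sum_k IC_{k,t}$ (fractional).
5. **Cows, non-reproductive:** binomial among *pregnant* cows with
   $p = 1/10$, the inverse of a 10-year working life.
6. **Mortality:** binomial over the whole herd and battery (1%/yr each);
   deaths trigger replacement purchases but earn no salvage revenue.

Because each bull runs the whole cascade independently, the total culled per
period is exactly $\mathrm{Bin}(BH, 1 - q)$ with $q$ the product of the
per-event survival probabilities. The stage-by-stage mean
$BH\,p_I + BH'\,p_{Test} + BH''\,p_{Age}$ (with $BH'$, $BH''$ the expected
survivors) is exact and equals $BH(1-q)$ — 18.4 of 40 bulls under BSE
defaults, 11.5 under NBSE. A stage-plug-in variance
$\sum n_e p_e (1-p_e)$ that holds each stage's eligible count at its
expectation is *not* the cascade's variance (it ignores that later stages see
a random number of survivors, and overstates the spread: 14.76 vs the exact
$40 \times 0.46 \times 0.54 = 9.94$); `expected_bull_culls()` returns the
exact variance and reports the stage-plug-in value separately as
`variance_stagewise`. The simulation-versus-closed-form agreement is tested
at 1% on $10^5$ draws, and the cascade distribution is checked against
brute-force enumeration by total-variation distance.

### Economics

Annual net cashflow nets calf revenue and cull salvage (cows at
1000 lb × \$0.86, bulls at 2000 lb × \$0.85) against replacement purchases
(heifers \$1,116, bulls \$7,250), bull maintenance (\$542.30/bull), and the
\$100/bull BSE fee. Cow maintenance is identical between strategies and
excluded by construction; all prices are held constant over the horizon. The
NPV discounts period $t$ at $(1+i)^{-t}$ for $t = 1..50$ with $i = 20\%$, a
cost of capital at the high end of agricultural enterprises. The first
production year is discounted one period; the alternative (a period-0
cashflow at exponent 0) rescales both strategies identically and cannot
change the sign of $\Delta NPV$.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `herd_size` | 1000 | cows | scalar giving whole-number bull batteries |
| `horizon` | 50 | yr | producer working lifetime |
| `discount_rate` | 0.20 | — | experimental evidence on farmer time preference |
| `breeding_cycles` | 3 | cycles | a ~63-d defined season, the conventional target |
| `fertility` (BSE) | 0.66 | /cycle | biological maximum for sound beef bulls |
| `abortion_rate`, `calf_death_loss` | 0.01 each | — | combined survival 0.9801, calibrated against the two-cycle revenue cells |
| `p_injury_cull` | 0.05 / 0.10 | /yr | 1-in-20 unscreened, doubled by handling for BSE |
| `p_test_fail` | 0.20 | /exam | fraction of presented bulls classed unsatisfactory |
| `p_age_cull` | 0.25 | /yr | inverse of 4-yr bull working life |
| `p_cow_nr_cull` | 0.10 | /yr | inverse of 10-yr cow working life |
| `p_cow_mortality`, `p_bull_mortality` | 0.01 | /yr | typical adult-cattle death loss |
| `iterations` | 500 | — | stabilises every $P(\Delta NPV>0)$ estimate |

The abortion and death-loss rates are not separately identifiable from the
deterministic revenue layer — only their product $\alpha\delta = 0.9801$
matters there — so the default splits the loss evenly at 1% each; both remain
configurable. The bull purchase price is the sale-data average \$7,250; a
producer quoting \$7,500 can set it in the `[budget]` section of the YAML
config.

## Monte Carlo design

Each scenario pairs a BSE strategy at fertility 0.66 with an NBSE strategy at
fertility $0.66 - d$, $d \in \{0, 0.01, \dots, 0.12\}$, for seasons of
$K \in \{2,\dots,6\}$ cycles and two cow:bull pairings — both strategies at
25:1, or BSE at 33:1 versus NBSE at 25:1 (screening is argued to let a
producer run fewer bulls). The full factorial is 130 scenario pairs
(`scenario_grid()`). Per iteration, the deterministic reproduction and calf
layers are shared computations; only culling and mortality are sampled.

Random draws come from named substreams: an integer seed is hashed with the
scenario, strategy, year, and event name, and iterations occupy vector lanes,
so iteration $i$ is identical whether run alone or inside a larger batch, and
results are reproducible from the manifest. By default the two strategies use
*independent* streams. A `common_random_numbers` flag reuses one stream for
both strategies' corresponding events, a variance-reduction pairing under
which two identical strategies tie exactly; it is an extension, not the
default, because the published design does not state common random numbers.
$\Delta NPV > 0$ is strict: exact ties count against screening.

The indifference point of a cumulative-probability curve is the fertility
difference at which $P(\Delta NPV > 0)$ first crosses 50%, located by linear
interpolation on the $d$ grid; curves already above 50% at $d = 0$ report
`"below_grid"`, curves that never reach it `"above_grid"`.

## What the deterministic grid reproduces — and what it does not

`deterministic_report()` emits the production grid — average cows bred,
calf-weighted weaning weight, and calf revenue by season length × fertility —
that explains most of the Monte Carlo orderings: lower fertility and longer
seasons mean fewer, later, lighter, cheaper calves. Display convention: cows
bred and revenue (thousands of \$) round *up* to the next whole unit — the
published table books a fractional expected cow as bred (its two-cycle,
66%-fertility cell is 885 for a 50-year mean of exactly 884.4) — while
weights round to nearest.

The two-cycle and three-cycle rows of the published reference table are
reproduced closely (the two-cycle rows exactly; three-cycle rows to within
one display unit). For seasons of 4–6 cycles the published rows are *not*
reproducible from the stated eligibility rule: systematic re-derivation —
including whole-cow rounding of each cycle's conceptions, alternative
placements of the "half eligible" cycle, capped ineligibility windows, and
both multiplicative and subtractive eligibility — shows the published long-
season rows are mutually inconsistent with the stated postpartum rule and
with each other, suggesting sheet-level formula drift in the original
spreadsheet implementation. This package implements the rule as stated. The
residual deviations are at most 8 cows, 6 lb, and \$13k on values of order
1000, under 1.3%, and do not affect the qualitative Monte Carlo results; the
acceptance suite asserts the published cells verbatim and records these rows
as known failures rather than tuning the model to hit them.

## Numerical choices

- Whole-unit displays guard against floating-point residue
  (`ceiling(round(x, 6))`), so `0.6 * 400` displays as 240, not 241.
- The eligibility formula short-circuits to 1 when $k + 2 > K$ (no cycles to
  lag) and when the previous year had no late conceptions.
- Non-reproductive culls draw on `round(pregnant)` trials, since binomial
  trials must be integers while the pregnant pool is a continuous
  expectation.
- Open-cow culls stay fractional through the revenue and replacement
  formulas; stochastic culls are integers.
- `indifference_point()` treats a curve touching 50% exactly as a single
  crossing and warns only on genuine non-monotonicity.
- Substream seeds stay below $2^{31}$ (R's integer range) by hashing modulo
  the prime $2^{31}-1$.

## What the simulated conditions do and do not show

The stochastic draws *are* the synthetic data of this study: there is no
field dataset. Passing tests therefore demonstrate internal consistency of
the bioeconomic model at the stated parameters — not that those parameters
describe any particular herd. Real operations have price risk, seasonal
nutrition effects, within-cohort weight variance, cow-side fertility
variation, and bull age structure, all deliberately out of scope; prices are
time-invariant, cull probabilities i.i.d. across years, and sex-differentiated
calf prices are ignored. Conclusions should be read as the published ones
are: qualitative orderings of $P(\Delta NPV > 0)$ across management settings,
robust to the exact event distributions, rather than point forecasts of
profit.

## Problem sizes used by the test suite

The deterministic grid is 65 cells of 50-year recursions and runs in well
under a second. The acceptance sweep runs the full 130-scenario factorial at
500 iterations; distributional checks use $10^5$ cascade draws and a
2,000-iteration exchangeable null. These sizes keep every
$P(\Delta NPV > 0)$ estimate's binomial standard error at or below 0.022
while the whole suite completes in seconds on one CPU.

## A worked comparison

```{r worked}
cfg <- herd_config()
pair <- scenario_grid(cycles = 3, fertility_diff = 0.05)[1, ]
run_simulation(pair, cfg, n = 500, seed = 1)
```

At a 3-cycle season, equal 25:1 ratios, and a 5-point fertility gap, the
extra culls and fees still outweigh the revenue gain in most iterations. The
indifference table over the full fertility range shows where that reverses:

```{r indiff}
sw <- sweep_scenarios(cfg, scenario_grid(cycles = 3), n = 500, seed = 1)
indifference_table(sw)
```

With both strategies at 25:1 the strategies break even near a 6.6-point
fertility difference; if screening lets the producer run 33:1 instead of
25:1, under a 2-point difference already favours screening.
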