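Package: herdsim
Title: Capital Budgeting Simulation of Bull Breeding Soundness Evaluation in
    Cow-Calf Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Bioeconomic simulation comparing two bull-battery management
    strategies for a commercial cow-calf operation: screening bulls annually
    with a breeding soundness evaluation (BSE) versus not screening (NBSE).
    Implements a deterministic expected-value recursion for the number of cows
    conceiving per estrus cycle under a lagged postpartum-anestrus eligibility
    rule, converts conceptions into weaned-calf revenue through a feeder-calf
    price slide, draws stochastic culling and mortality events from sequential
    binomial cascades, assembles annual net cashflows, and discounts them to
    net present value (NPV) over a 50-year planning horizon. A Monte Carlo
    engine estimates the probability that the BSE strategy is more profitable,
    P(dNPV > 0), across breeding-season lengths, fertility differences, and
    cow:bull ratios, and locates the fertility difference at which the two
    strategies are financially equivalent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
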