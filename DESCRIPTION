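Package: eamsim
Title: Agent-Based Simulation of Educational Assortative Mating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based marriage-market model of educational assortative
    mating. Agents search for spouses under gender-specific preferences for
    educational similarity, earnings prospects and partner age; meeting
    opportunities are structured by school enrolment; commitment, age
    pressure, divorce, mortality and cohort replacement drive the dynamics.
    The package builds agent cohorts from education and earnings schedules
    (user-supplied CSV tables or a built-in synthetic generator emulating the
    reversal of the gender gap in tertiary education), runs replicated
    discrete-time simulations with a compiled scheduler, and computes the
    standard outcome measures: hypergamy, homogamy and hypogamy shares by
    birth cohort, the index of female educational advantage, random-mating
    baselines, and parameter-knockout experiment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    dplyr,
    tidyr,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
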