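---
title: "An agent-based marriage market for educational assortative mating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based marriage market for educational assortative mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eamsim)
```

## The model

`eamsim` simulates a two-sided marriage market in discrete time (ten steps
per simulated year). Each agent carries a gender, an age in steps, an
ultimate educational attainment on a 4-level scale (none, primary,
secondary, tertiary) fixed at birth, an earnings-prospect category on a
5-level ordinal scale fixed at birth, a school enrolment status that
follows deterministically from age and ultimate education, a relationship
state (single, dating, married) with a partner link and a relationship
duration, and an ideal partner age.

Behaviour is governed by six small equations, all exposed as vectorised R
functions and shared with the compiled scheduler:

* **Mate value.** The attractiveness of candidate $j$ to observer $i$ is
  $v_{ij} = \left(\frac{S_{max}-|s_i-s_j|}{S_{max}}\right)^{w_s}
  \left(\frac{y_j}{Y_{max}}\right)^{w_y}
  \left(\frac{A_{max}-|\alpha_i-a_j|}{A_{max}}\right)^{w_a}$,
  a product of power-weighted similarity in education, the candidate's
  earnings prospects, and closeness to the observer's ideal partner age.
  Weights are gender-specific; a zero weight neutralises its factor
  ($0^0 = 1$), and the age base is clamped at zero. All ages enter in
  steps, so a one-year age deviation costs a factor $(790/800)^{w_a}$.
* **Search.** An agent actively seeks a meeting with probability
  $e^{-c\beta}$, where $c$ is its current relationship duration in steps;
  singles ($c = 0$) always search.
* **Structured meeting.** With probability $\delta$ the candidate is drawn
  uniformly from opposite-gender marriageable agents sharing the seeker's
  school enrolment status, otherwise uniformly from the complementary
  subset (an empty subset falls back to the other). This implements the
  idea that schools are local marriage markets: the longer people stay in
  education, the more their meeting pool resembles their own ultimate
  attainment.
* **Dating.** Each side of a meeting accepts with probability
  $(1-e^{-a v \sigma})\,e^{-c\beta}$: age pressure ($\sigma$) makes older
  agents less selective, commitment to an existing partner attenuates
  switching. Partnered agents consider only candidates whose mate value
  strictly exceeds their current partner's; a mutual acceptance dissolves
  both previous relationships (the model's divorce mechanism).
* **Marriage.** Each member of a dating couple proposes (or becomes
  willing to accept) with probability $(1-e^{-a v \sigma})(1-e^{-c\beta})$
  per step. A proposal stands until accepted, or until breakup or death.
  The couple marries when both sides have proposed; duration continues
  accumulating from the start of dating.
* **Mortality.** Each step an agent dies with probability
  $0.1\,d\,(a/A_{max})^{w_d}$; survivors reaching $A_{max} = 800$ steps
  (age 80) are removed. Each agent leaving the population is immediately
  replaced by a same-gender newborn whose education and earnings are drawn
  from the current year's cohort schedule, which keeps population size and
  gender balance exactly constant.

## Parameters and defaults

Defaults are the calibrated full-model values: $\delta = .9$,
$w_s = (.934, .385)$, $w_y = (1.025, 1.201)$, $w_a = (5.009, 10.833)$
(male, female), $\beta = .015$ for both genders, $\sigma = (.0015, .0030)$,
$d = .1$ and $w_d = 6$. With these mortality parameters the chance of
dying within a year reaches 10% at age 80 (ten steps of 0.01; compounded
survival gives $1-(1-.01)^{10} \approx 9.56\%$ — the model uses the
per-step form and the 10% figure refers to the linear aggregation).
Men hold a fixed ideal partner age of 24 years (240 steps); women prefer
partners 2.5 years (25 steps) older than themselves, recomputed as they
age. We treat the female ideal age as age-dependent even though agents'
ideal age is nominally a birth attribute: a birth-fixed value of 25 steps
would mean every woman ideally partners a toddler, so the offset rule is
the only sensible reading. Agents become marriageable at 16 (160 steps).
`preference_params(ideal_age_rule=)` can impose either rule on both
genders, which is how fully gender-symmetric configurations are expressed.

`dynamics_params()` accepts $\beta = 0$ and $\sigma = 0$ as meaningful
boundary cases (no commitment dynamics; no dating at all), used by the
test suite.

## Scheduling

One step executes, in order: ageing (and removal at the ceiling),
mortality draws, widow/ex-partner resets, replacement births, enrolment
refresh, the search phase over marriageable agents in a freshly shuffled
order, marriage decisions for dating couples, and a final duration
increment for all partnered agents. Deaths precede search so nobody dates
a removed agent; durations increment last so $c$ counts completed steps
together. Each seeker makes one meeting attempt per step; meetings are
asymmetric (the candidate need not be seeking) and conflicts resolve in
processing order, so a couple formed early in a step can be broken later
in the same step by a better alternative. Ties in mate value never
trigger a switch. The census at the end of each census year records all
currently married couples.

All randomness flows through R's RNG in a documented draw order, so a
replicate is fully reproducible from its seed; replicate $r$ of a run
uses `base_seed + r - 1`.

## Synthetic cohort schedules

Real applications initialise agents from reconstructed education
distributions per birth cohort and gender, paired with survey-based
earnings distributions per gender and education; `read_schedules_csv()`
accepts any such pair of tables. The built-in generator emulates the two
stylised facts those inputs carry, with logistic trends in cohort birth
year:

* the male tertiary share expands from 5% to 30% (midpoint 1955), and the
  female share equals the male share plus
  $0.14\tanh((y-1965)/18)$, so women trail men in tertiary education
  before the 1965 birth cohort and overtake them after it — a reversing
  gender gap with the crossing at `crossover_year`;
* 'no education' declines from 12% to 0.5% and 'primary' from 50% to 6%,
  with the remainder in 'secondary'; the three are renormalised against
  the tertiary share so every cohort distribution is a valid simplex;
* earnings categories follow a shifted binomial, $1+\mathrm{Bin}(4,p)$,
  with the female mean category rising from 2.0 to 3.6 across education
  levels and the male mean equal to the female mean scaled by
  `earnings_advantage` (default 1.25, in the range of observed
  male/female income ratios within education levels), capped at the top
  category. Advantage 1 gives identical distributions; advantage > 1
  makes the male distribution stochastically larger.

The generator reproduces the qualitative shape of educational expansion,
not any particular country. Passing tests on these schedules shows the
mechanisms behave correctly under realistic composition shifts; it does
not certify country-level quantitative fit, which requires the real
reconstruction data.

## Outcome measures

Couples are classified on a merged 3-category scale (none+primary = low,
secondary, tertiary), since the lowest category is nearly empty in the
data the model emulates: hypergamic when the wife's merged level is lower
than the husband's, homogamic when equal, hypogamic when higher.
`couple_shares()` tabulates shares in half-open decade bins of birth year,
by default (1940,1950] through (1970,1980]. Shares are respondent-based:
each married agent born in a bin contributes one observation, so a couple
spanning two decades contributes to both (a couple-based mode is available
via `unit = "couple"`). The F index of female educational advantage and
the expected random-mating shares are computed exactly from their
closed-form definitions on the merged margins. Replicate aggregation
reports unweighted means and sample standard deviations across replicates.

## Design notes and numerical choices

* The $\delta$-stratification applies literally to all five enrolment
  states, including 'finished'. A consequence worth knowing: $\delta = .5$
  is *not* equivalent to a uniform draw from the pool. The two-set rule
  oversamples whichever enrolment subset is smaller; for example, a young
  low-educated agent who has already left school draws an in-school (and
  hence more educated) candidate with probability .5 even though in-school
  agents are a small minority of the pool. Under knocked-out preferences
  this channel produces couple-type shares that sit a few points away
  from the textbook random-mating expectation (homogamy about 2 points
  low on the default schedules); with a configuration in which all
  marriageable agents share one enrolment status, simulated shares match
  the random-mating formulas within Monte-Carlo error. The test suite
  records both facts.
* Initial populations draw ages uniformly on $[0, A_{max})$; the census
  cohorts (born 1941–1980) are entirely born in-simulation, so the
  initial age structure washes out during burn-in. Cohorts born before
  the first scheduled year inherit the first year's distribution.
* Replacement samples education from the current year's schedule, so
  realised cohort composition is multinomially random around the
  schedule rather than quota-matched.
* Probabilities act as independent per-step Bernoulli draws; no
  carry-over of unspent probability.
* A simulated year spans ten steps; the default run covers 1921–2012
  inclusive (920 steps) with 250 agents per gender, and censuses are
  pooled from the ends of 2010 and 2012. One replicate at this size takes
  well under a second; the replicated comparisons in the test suite use
  30 replicates per condition.

## Knockout experiments

`run_experiment()` compares five presets on a common schedule: the
calibrated full model and four single-mechanism knockouts
($w_s = 0$; $\delta = .5$; $w_a = 0$; $w_y = 0$). On the default synthetic
schedules the full model yields pooled shares of roughly 15% hypergamy,
69% homogamy and 16% hypogamy across the census cohorts, and the
knockouts move homogamy in the expected directions: removing education
preferences or meeting structure lowers it substantially, removing
earnings or age preferences raises it. Under these synthetic schedules
the earnings and age knockouts land at statistically indistinguishable
homogamy levels (their replicate distributions overlap almost entirely),
so the relative ranking of those two mechanisms is schedule-dependent
rather than a robust model property.

```{r experiment, eval = FALSE}
sched <- generate_synthetic_schedules()
cfg <- simulation_config(n_replicates = 30, base_seed = 1)
run_experiment(sched, cfg)
```

## Limitations

The model has no fertility-driven birth counts, migration, cohabitation
distinct from dating, remarriage penalties, or within-gender preference
heterogeneity; preferences are constant over time by construction — that
is the point of the exercise, which asks how much of the observed change
in assortative mating follows from composition alone. Earnings are
ordinal categories, not amounts. The synthetic generator does not emulate
country idiosyncrasies, wars, or education reforms; quantitative
reproduction of observed country-level shares requires the real cohort
reconstruction inputs via `read_schedules_csv()`.
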