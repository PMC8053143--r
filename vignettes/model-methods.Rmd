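---
title: "Model and methods: microsimulation of sequential teriparatide/alendronate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Teriparatide is an anabolic agent with strong anti-fracture efficacy and a
high price; in Japan a biosimilar has been available since late 2019 at 70%
of the brand price. For women at high fracture risk the clinically natural
strategy is 2 years of daily teriparatide (the regulatory maximum) followed
by 8 years of weekly alendronate, compared against 10 years of alendronate
alone. `osteocea` implements an individual-level state-transition
(microsimulation) model of this comparison for community-dwelling Japanese
women with a prior clinical or morphometric vertebral fracture, starting at
ages 70, 75 or 80, with annual cycles to death or age 105.

Each simulated woman carries her own history: fracture counts (at most two
hip fractures, unlimited clinical vertebral fractures; at most one fracture
per cycle), time since the last hip fracture, treatment phase and year, and
offset status after stopping therapy. Costs accrue to two sectors — public
healthcare and public long-term care — so both the combined-payer primary
perspective and the healthcare-only sub-analysis can be reported from one
run.

## Cycle semantics

Within a cycle the engine samples, in order:

1. **Treatment continuation.** A woman on a drug persists through the year
   with the annual continuation probability `S(y)/S(y-1)` implied by the
   cumulative persistence curve. A discontinuing woman receives no
   protection that cycle (benefit requires persisting to the cycle's end)
   and enters the offset phase the following cycle.
2. **Effective relative risk.** Persisting women get
   `1 - adherence(y) * (1 - RR_trial)` — efficacy scales linearly with
   adherence. Offset-phase women get a multiplier that interpolates linearly
   from the last on-treatment value to 1 over the offset length.
3. **Fracture.** Hip first (if below the two-fracture cap), then vertebral
   conditional on no hip. Hip precedence when both would occur is a model
   choice: hip is the clinically dominant event and the source material
   forbids two fractures per cycle without naming a tie-break.
4. **Death.** Sampled after the fracture so that the within-a-year excess
   hazard (relative hazard 2.87, attributable fraction 0.25) applies in the
   fracture cycle itself; from the next cycle onward the lifelong relative
   hazard 1.73 applies. A recurrent hip fracture resets the within-a-year
   clock. Vertebral fractures carry no excess mortality in the base case;
   the `vert_excess_mortality` scenario gives them the hip parameters.
5. **Accounting.** Utility is the age-band EQ-5D baseline times lifelong
   multiplicative disutilities (first-year multiplier in a fracture cycle,
   beyond-first-year multiplier afterwards; hip and vertebral combine by
   multiplication). A death cycle contributes zero utility, and books only
   the fracture treatment cost and long-term-care cost — no treatment
   resource use. Discounting uses integer-cycle exponents with the first
   year undiscounted.

Events are end-of-cycle and no half-cycle correction is applied, matching
the annual-cycle design of the source analysis.

## Treatment schedules

* Alendronate cumulative persistence is anchored at 55% (year 1) and 10%
  (year 7). The interpolation rule between the anchors is not stated in the
  source; we use a constant annual continuation ratio `(0.10/0.55)^(1/6)`
  (geometric decline), the standard constant-hazard reading. From year 8 to
  10 there is no dropout except death. Teriparatide persistence is 68.0% /
  51.6% at years 1 / 2.
* Alendronate adherence declines linearly from 70.6% (year 1) to 60.9%
  (year 5) and is flat afterwards; teriparatide adherence is 70.2% then
  67.8%. The tabulated first-year values are rounded (0.70/0.71); we use the
  precise values from the running text since they define the schedule
  construction.
* In the sequential strategy, a completer of 2 years of teriparatide starts
  the alendronate schedules at their year-1 values (no carry-over rule is
  stated; restarting is assumed and the alendronate first-visit fee is
  charged at the switch). A woman who *discontinues* teriparatide does not
  start alendronate — the offset rule is written for women who took
  teriparatide without starting alendronate afterwards — and her offset
  length is proportional to time on drug (zero years taken makes the offset
  vacuous).
* The alendronate offset equals its treatment duration (8 years sequenced,
  10 years as monotherapy); the teriparatide offset is 2 years (3 in the
  scenario analysis).

## Costs

While persisting: annual drug cost × adherence, the yearly prescription
charge, four physician visits (the first visit of each drug at the
first-visit fee), two blood tests (¥2,900 each), and a DXA scan (¥4,500) at
the end of overall treatment years 2, 5 and 10 (charged only while still on
treatment). First-year discontinuers are charged a single 3-month fill
(annual cost / 4) and one visit; later-year discontinuers one visit only.
Monitoring stops with treatment; the offset phase is free.

Fracture treatment: hip ¥1,726,000; first in-model clinical vertebral
¥420,000 (regardless of the baseline prior fracture); subsequent vertebral
¥842,000. Long-term care: ¥876,000/yr post-hip, else ¥213,000/yr
post-vertebral, half in the cycle of the state-defining fracture. When both
states exist we charge the hip amount only, not the sum — the two state
costs describe care for the same person and summing would double-count;
this is one of the deliberately isolated structural choices (see
`cycle_costs()`).

## Parameters, ranges and distributions

Every parameter is addressable by a stable identifier (`param_ids()`), with
its base value, one-way range and probabilistic distribution held in
`param_registry()`. Distribution choices follow the published table:

* Efficacy relative risks and disutility multipliers: beta distributions
  fitted so the 2.5%/97.5% quantiles equal the published 95% CI bounds
  (`fit_beta_from_ci()`, numerical two-parameter root-find, tolerance 1e-6).
  Only the bounds are published, so mean and mode are not separately
  constrained.
* Prior-fracture relative risks and post-hip mortality relative hazards:
  gamma distributions fitted the same way.
* Published "± X%" ranges: triangular distributions with the base value as
  mode and multiplicative bounds. Adherence ranges are first-year bounds
  carried to later years as bound-to-base ratios; adherence and persistence
  values implied above 1 are capped at 1. The fracture medical-cost block
  and the long-term-care block each vary as a single grouped multiplier
  (matching the single printed range per block), baseline utilities as one
  multiplier, and the discount-rate triangular (0–4%) moves cost and QALY
  discounting jointly.
* Hip and vertebral efficacy are sampled independently per drug (the
  source does not state a joint draw).

## Mortality input and the synthetic stand-in

The source model took annual death probabilities from the official 2018
Japanese female abridged life table, which is external data this package
does not embed. `read_life_table()` accepts a single-year `age,qx` CSV, or
an abridged 5-year table which is expanded assuming constant `qx` within
each band (the source does not state how the abridged table was used;
single-year expansion is assumed).

`make_synthetic_life_table()` provides a calibrated stand-in from a
Gompertz–Makeham hazard, `qx = 1 - exp(-(c + a e^{b·age}))`, with defaults
`a = 1e-5`, `b = 0.11`, `c = 2e-4`. Gompertz–Makeham is the standard
monotone family for adult human mortality, and the default calibration is a
fixture chosen so that death by age 105 from any starting age exceeds 99% —
the direction the validation arm checks — not an estimate of Japanese
mortality. Its mortality is substantially heavier than contemporary
Japanese female mortality, so lifespans (and with them lifetime fracture
probabilities, QALY totals and ICERs) are smaller than published values.
Tests that pass on the stand-in therefore demonstrate the mechanics of the
model — schedules, event logic, accounting, economics — and the validation
direction, but not numerical reproduction of the published table; the
reproduction-tier checks in `test-acceptance.R` document that gap rather
than hiding it, and exact reproduction requires supplying the real life
table.

## Numerical and design choices

* Person-year incidence rates convert to probabilities by `1 - exp(-r)`;
  at these magnitudes the difference from using the rate directly is below
  1%.
* Prior-vertebral-fracture relative risks (2.3, 4.4) are a cohort-level
  multiplier applied from baseline onward and are not compounded by
  in-model fractures.
* Common random numbers: each cycle draws four uniforms per woman whether
  or not she is alive or at risk, so runs with equal seeds are aligned
  draw-for-draw across strategies, sweep grid points and scenarios. Every
  sweep reproduces the base case bit-for-bit at its identity grid point.
* The within-a-year excess hazard is applied in the fracture cycle itself;
  the choice is isolated in `mortality_multiplier()` for easy flipping.
* Dominance in `compare_strategies()` is labelled, never silently divided:
  extra cost at zero QALY gain is reported as dominated (infinite ICER).

## Problem sizes

The test suite and the acceptance script choose simulation sizes to balance
Monte-Carlo error against runtime on a single CPU: 200,000 women for the
two-cycle enumeration oracle (exact expected values versus simulated means,
with a Šidák-corrected 3-SE family criterion across the nine comparisons),
20,000 for base-case and validation reproduction checks, 10,000 per price
grid point, 100 simulations × 4,000 trials for the acceptability-curve
check, and 100,000 per starting age in `scripts/acceptance.R`. The full
published design (100,000 iterations; 1,000 simulations × 100,000 trials
for the PSA) is available by passing the corresponding arguments.

## Limitations

Only hip and clinical vertebral fractures are modelled (no forearm or
humerus fractures, no adverse events, no BMD covariate); baseline prior
vertebral fracture affects risk but carries no cost or disutility of its
own; there is no individual heterogeneity beyond stochastic histories; and
the societal perspective is out of scope. The synthetic mortality stand-in
is a fixture, not Japanese mortality, as discussed above.
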