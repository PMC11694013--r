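---
title: "Methods: partitioned life-expectancy estimation with misclassification-corrected deaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned life-expectancy estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tenamericas)
library(dplyr)
```

## The estimation problem

National mortality statistics stratified only by race, or only by
geography, hide how strongly the two interact. The ten-Americas design
addresses this by partitioning all county × race/ethnicity units into
ten mutually exclusive, collectively exhaustive groups and estimating
period life expectancy for each. Three data problems stand between the
raw inputs and defensible estimates, and this package implements the
standard treatment of each:

1. **Numerator–denominator inconsistency.** Race/ethnicity on death
   certificates is recorded by funeral directors and sometimes differs
   from self-identification, while population denominators reflect
   self-report. Dividing the one by the other biases race-specific
   rates. The remedy is a population-level correction: multiply
   recorded-race death tabulations by a misclassification ratio
   (deaths tabulated by self-report ÷ deaths tabulated by recorded
   race).
2. **Inconsistent race categorisation over time.** Later death records
   and recent census products carry a "Two or More Races" category that
   earlier years lack; both deaths and population are bridged onto
   single-race categories.
3. **Census-base discontinuities.** Postcensal population estimates
   based on one census disagree with the series based on the next; the
   discrepancy is blended away in the style of intercensal estimation.

Uncertainty from the correction and from the stochastic variation of
death counts is propagated by Monte-Carlo simulation through abridged
life tables; every reported quantity is the mean of the simulation
draws with a 2.5th–97.5th percentile uncertainty interval.

## Classification rules

`classify_americas()` applies, per race/ethnicity:

* Latino: America 5 in the Southwest (AZ, CO, NM, TX), else America 2.
* Asian/NHPI (carried as one combined label; the two cannot be fully
  separated in early-period death data): America 1 where NHPI are less
  than 30% of the combined Asian+NHPI population, else America 3.
* AIAN: America 10 in the 14 interior-West states, else America 3.
* Black: America 7 in highly segregated (dissimilarity ≥ 60),
  high-population metropolitan (RUCC 1) counties; America 9 in
  non-metropolitan (RUCC 4–9), low-income counties of the Lower
  Mississippi Valley or Deep South; else America 6.
* White: America 4 in non-metropolitan, low-income Northlands counties
  (IA, MN, MT, NE, ND, SD); America 8 in low-income Appalachia or
  Lower Mississippi Valley counties; else America 3.

Thresholds are deliberately asymmetric: the segregation cut is
inclusive (≥ 60, "60 or higher") while the income cut is strict
(< \$32,363, "below the median"). The America 7/9 rules are mutually
exclusive under valid RUCC codes (a county cannot be both code 1 and
codes 4–9); the implementation nevertheless fixes 7-before-9 and
4-before-8 precedence so the map stays deterministic on malformed
inputs. The dissimilarity index is computed from subunit counts as
`D = 50 Σ|bᵢ/B − wᵢ/W|`, 0 for identical distributions, 100 for
complete segregation; a zero group total makes the index undefined and
is an error rather than a silent 0.

## The misclassification correction

For each race the correction starts from a ratio table with standard
errors, available overall and by age–sex band, census region, and
co-ethnic density tercile (the county-level concentration of the
group's population — applied to Latino and AIAN only, where
misreporting is known to vary with concentration; other races carry a
single density stratum).

**Simulation of ratios.** Each ratio generates `n_sims` (default 1000)
log-normal draws moment-matched on the arithmetic scale: with reported
mean $m$ and standard error $s$,
$\sigma^2 = \log(1 + s^2/m^2)$, $\mu = \log m - \sigma^2/2$, so the
draws' arithmetic mean is $m$ and their arithmetic SD is $s$. A zero SE
produces draws exactly equal to the mean. The arithmetic (not log-scale)
matching is deliberate: the ratio and its SE are reported on the
natural scale.

**Combination across dimensions.** Per simulation $s$ the applicable
components are combined as multiplicative deviations from the overall
race-level ratio:
$\mathrm{combined}_s = \mathrm{overall}_s \prod_d
\mathrm{component}_{d,s} / \mathrm{overall}_s$.
This satisfies the two anchoring cases — all components equal to the
overall ratio collapse to it, and a single deviating dimension passes
through unchanged — and is isolated in `combine_ratio_dimensions()` so
an alternative interaction rule can replace it without touching
callers. How dimension interactions should be handled beyond these
anchor cases is genuinely open; the multiplicative rule is the simplest
member of the family that respects them.

**Application and rescaling.** Recorded deaths are multiplied by the
combined draw, then every year × county × age × sex × simulation
stratum is rescaled by `raw total / corrected total`. The correction
therefore only ever moves deaths *between* race groups within a
stratum, never changes how many deaths occurred — conservation is exact
by construction and asserted to 1e-9 relative in the tests. A stratum
whose corrected total would be zero while raw deaths exist is an error.

**Stochastic variation.** After aggregation to America level, each
(cell, simulation) death count is replaced by one Poisson draw with the
corrected value as its rate. Each simulation index uses an independent
stream derived from the root seed, so results are reproducible and do
not depend on evaluation order across simulations.

## Population harmonisation

`split_two_or_more_races()` allocates the multirace category
proportionally to the cell's single-race composition (totals conserved
exactly). `intercensal_blend()` removes the census-base discontinuity:
with discrepancy $\Delta$ at the base year, the pre-base series becomes
$x(t) + w(t)\,\Delta$ with $w$ rising linearly from 0 at the window
start to 1 at the base year (`linear_additive`, the default), or
equivalently multiplies by the base-year ratio raised to $w(t)$
(`linear_multiplicative`). The actual intercensal methodology has
several variants; the blend function is a pluggable strategy precisely
so the exact method can be substituted. The discrepancy itself is
computed per cell (county × age × sex × race) rather than in aggregate,
because the downstream rates are cell-level;
`estimate_base_discrepancy()` obtains the old-series value at the base
date by log-linear extrapolation of the four preceding years. Cells an
additive blend would drive negative are floored at zero and counted in
a message.

## Life tables

Rates are computed **after** pooling deaths and population to America
level (the rate of pooled counts, not a mean of county rates). The
abridged schema is 0, 1–4, five-year groups to 80–84, and open 85+ —
19 groups. Conversions follow the standard abridged conventions:
`q = n·m/(1 + (n − a)·m)` capped at 1, `a = n/2` in closed groups with
the infant exception `a(0) = 0.07 + 1.7·m(0)` (a Coale–Demeny-style
rule appropriate when infant deaths concentrate early in the first
year), radix 100,000, `L = n·l(x+n) + a·d(x)`, `T` by reverse
cumulative sum, `e = T/l`.

The open 85+ group is closed by a strategy:

* `constant_hazard` (default): `e(85) = 1/m(85+)`, the stationary
  value. This is the validated default used throughout the tests.
* `horiuchi_coale`: a growth-corrected estimate for non-stationary
  populations. Rather than transcribing regression coefficients, the
  implementation works from the stable-population rationale of the
  method: it calibrates a Gompertz hazard above 85 (slope 0.1/year by
  default) so that the stable population with growth rate $r$
  reproduces the observed terminal death rate, and returns that
  hazard's stationary life expectancy. At $r = 0$ it equals `1/m`
  exactly (verified in tests); positive growth implies a younger
  terminal age distribution, hence a lower stationary expectancy for
  the same observed rate. Both strategies are strictly decreasing in
  `m`.

Partial (temporary) life expectancy over $[x_1, x_2)$ is
$(T(x_1) - T(x_2))/l(x_1)$ — the mean years lived in the range by
those alive at $x_1$, bounded by the range width. Note that because
each partial conditions on survival to its own $x_1$, the telescoping
reconstruction of $e_0$ weights every term by $l(x_1)/l(0)$, not just
the terminal term; the tests assert that weighted identity to 1e-9.
Requests with $x_1$ at the open group are rejected: remaining life
expectancy at 85 is a different quantity, reported separately.

Percentiles across the (by default 1000) simulation draws use linear
interpolation between order statistics — with only 1000 draws the
percentile definition materially affects the interval, so it is pinned
down and oracle-tested.

## The synthetic generator

`sim_config()` / `generate_*()` emulate the statistical structure the
analysis assumes, not any real data product:

* counties with state, RUCC (1–9), a dissimilarity index computed from
  simulated tract weights (a share of counties gets strongly clustered
  settlement patterns so highly segregated metros exist), NHPI share
  (Beta(2, 8): most counties Asian-dominant), race-specific incomes
  (log-normal, centred so a configurable fraction — default 0.5 —
  falls below the \$32,363 threshold), and regional flags (Deep South
  deterministic by state; Appalachia and Lower Mississippi Valley
  sampled with state-specific probabilities, because the real county
  lists are external resources);
* a smooth population series (county size × Dirichlet race mix ×
  declining age profile × constant county growth) with a census-base
  jump of configurable mean absolute size (default 3%, sign random per
  county × race series) and a "Two or More Races" category (default 3%
  of each cell) from the base-change year on;
* deaths drawn per cell as Poisson with rate
  population × Gompertz–Makeham hazard `h(x) = c + a·e^{bx}`, with
  race-specific parameters spanning life expectancies from the low 70s
  (AIAN) to the mid 80s (Asian/NHPI) and a 1.4× male hazard ratio —
  Poisson rather than binomial deaths match the pipeline's downstream
  Poisson assumption;
* misreporting as a per-death categorical draw from a row-stochastic
  matrix (defaults concentrate flow in AIAN→White, the dominant
  direction in linkage studies, giving an AIAN ratio near 1.28);
* ratios derived from the true/recorded tabulations with delta-method
  standard errors for a ratio of Poisson totals,
  `se = ratio·√(1/num + 1/den)` — a stand-in for linkage-study SEs,
  flagged as such in the config (`ratio_se_method`).

What the generator does **not** emulate: real geographic settlement
patterns (states are uniform, regional flags probabilistic), ICD cause
coding, record layouts, within-county population structure beyond the
tract weights the dissimilarity index needs, age- or dimension-varying
misreporting (the default matrix is constant across ages, regions and
density), and NHPI-specific estimation. Passing tests therefore
demonstrate that the machinery is correct and calibrated under the
assumed data-generating process — not that the correction removes bias
in real data, where misclassification patterns are more heterogeneous.

## Calibration evidence

`parameter_recovery_study()` repeatedly simulates a year of vital
statistics with known hazards and misreporting, runs the full
correction and life-table pipeline, and scores it against the truth
implied by the expected mortality rates:

```{r recovery, eval = FALSE}
rs <- parameter_recovery_study(n_replicates = 200, n_sims = 100)
rs$summary
```

Two properties are asserted at scale in the test suite: the corrected
life expectancy for the AIAN-only America is substantially less biased
than the uncorrected one (the whole point of the correction), and the
95% uncertainty intervals cover the truth at close to their nominal
rate (90–98% pooled over Americas and replicates).

## Problem sizes and defaults

The package defaults describe the conditions the methods are exercised
under: 200 synthetic counties (the smallest count that reliably
populates all ten Americas), five race/ethnicity labels, seven recent
years spanning the 2020 base change, 1000 simulation draws for
uncertainty (tests and the recovery study use 100–250 draws, which is
ample for the point estimates and calibration checks they make), and
200 recovery replicates. All randomness flows from explicit integer
seeds; fixed seeds give byte-identical outputs.

## Known limitations

* The dimension-combination rule and the delta-method SEs are
  documented stand-ins for external methods the package cannot
  reproduce; both are isolated behind single functions.
* The published reference estimates in `inst/extdata/` are transcribed
  inputs: the pipeline cannot re-derive them because the national
  microdata are restricted. One printed value (the 2010 gap, 13.9) is
  internally inconsistent with its own rounded levels (14.0); the
  reporting tests accept it within one rounding step and the reference
  loader preserves the printed levels untouched.
* County boundaries are stable over time in the synthetic world; the
  real analysis merges a small number of changed counties.
* Sex-stratified output is produced but only property-tested; the
  transcribed reference surface is both-sex only.
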