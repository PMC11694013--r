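# tenamericas

Mortality disparities in the USA are much larger between certain
combinations of place and race/ethnicity than between either dimension
alone. `tenamericas` implements a reusable pipeline for the "ten
Americas" design: every county × race/ethnicity unit in the country is
assigned to exactly one of ten mutually exclusive, collectively
exhaustive population groups — defined by race/ethnicity together with
geography, metropolitan status, county income, and Black–White
residential segregation — and period life expectancy is estimated for
each group with full uncertainty propagation.

The package is aimed at demographers and population-health researchers
who want to reproduce, stress-test, or adapt this style of analysis.
Because the underlying vital-statistics microdata are restricted, the
package ships a synthetic vital-statistics generator that emulates
their statistical structure (stratified death and population counts, a
race-misreporting process on death records, a census-base discontinuity
in the population series, and a "Two or More Races" category), so every
stage is testable end to end at desk scale.

## What it computes

**Classification.** A county is *high-population metropolitan* iff its
USDA Rural–Urban Continuum Code (RUCC) is 1, *non-metropolitan* iff
RUCC ∈ 4–9, *highly segregated* iff its Black–White dissimilarity index

D = 50 · Σᵢ | bᵢ/B − wᵢ/W |

is ≥ 60, and *low-income* for a group iff that group's county income
per capita is below \$32,363 (the median all-race county income per
capita in 2020). `classify_americas()` applies the ten definitional
rules and `validate_partition()` proves the result is a partition.

**Death adjustment.** Race/ethnicity on death certificates is sometimes
misclassified relative to self-identification, biasing race-specific
mortality rates. The pipeline corrects tabulated deaths with
misclassification ratios (self-reported ÷ certificate-recorded deaths),
propagating their uncertainty by drawing 1000 log-normal simulations
per ratio (moment-matched: σ² = ln(1 + se²/m²), μ = ln m − σ²/2),
combining ratios across dimensions (age–sex, census region, co-ethnic
density) as multiplicative deviations from the overall race-level
ratio, and rescaling within each year × county × age × sex × simulation
stratum so the correction never changes the total number of deaths.
A Poisson layer then adds the stochastic variation of observed counts.

**Population adjustment.** "Two or More Races" population is split onto
single-race categories in proportion to local composition, and the
census-base discontinuity is removed by an intercensal-style blend that
phases the base-year discrepancy in linearly over the preceding decade
(additive or multiplicative).

**Life tables.** Deaths and population are pooled to America level and
abridged life tables (ages 0, 1–4, 5-year groups to 80–84, then 85+)
are built per year, America, sex and simulation:
q = n·m / (1 + (n − a)·m), a(0) = 0.07 + 1.7·m(0), radix 100,000, with
the open 85+ group closed by a terminal-rate strategy (`1/m`, or a
growth-corrected stable-population variant). Reported quantities are
life expectancy at birth (e0), partial (temporary) life expectancy for
0–4, 5–24, 25–44, 45–64 and 65–84, and remaining life expectancy at 85,
each summarised as the mean of the simulations with a 95% uncertainty
interval (2.5th–97.5th percentile).

**Reporting.** Gap, change and ranking statistics over any
life-expectancy grid, including the transcribed published estimates
shipped in `inst/extdata/` as a fixed reference surface.

## Worked example

```r
library(tenamericas)
library(dplyr)

# disparities in the published reference estimates
grid <- load_published_life_expectancy()
compute_gap(grid, 2021)
#>    year   gap   max   min america_max america_min
#> 1  2021  20.4    84  63.6           1          10
```

The 2021 gap between the highest group (America 1, the predominantly
Asian population, 84.0 years) and the lowest (America 10, AIAN in the
West, 63.6 years) is 20.4 years.

```r
# full synthetic pipeline: generate → classify → correct → life tables
cfg <- sim_config(n_counties = 200, years = 2020:2021, seed = 1)
run <- run_pipeline(cfg, n_sims = 100, sexes = "both")
run
#> <ten_americas_run> 200 counties, 100 simulations, seed 1
#> # A tibble: 10 × 4
#>    america_id  mean lower upper
#>         <int> <dbl> <dbl> <dbl>
#>  1          1  84.1  83.1  85.3
#>  2          2  79.7  79.4  80.2
#>  3          3  76.0  75.9  76.2
#>  4          4  76.2  75.4  77.1
#>  5          5  79.1  78.4  79.8
#>  6          6  71.9  71.4  72.2
#>  7          7  71.6  70.7  72.4
#>  8          8  76.4  76.1  76.6
#>  9          9  72.2  71.2  73.5
#> 10         10  72.3  71.1  73.5
```

Each row is one America's life expectancy at birth in the final
simulated year (mean over 100 simulation draws, with the 95%
uncertainty interval). The synthetic hazards are parameterised so the
groups span a realistic range; `tidy(run)` returns the full grid of
e0, partial life expectancies and e85 by America, year and sex, and
`plot_life_expectancy(tidy(run))` draws the trends.

```r
# a single abridged life table
lt <- build_life_table(rep(0.0125, 19))
glance(lt)$e0
#> [1] 79.97  # constant hazard m: e0 ≈ 1/m = 80
```

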