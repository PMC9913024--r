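---
title: "Percentile-based scenario targets for contraceptive coverage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percentile-based scenario targets for contraceptive coverage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpscenarios)
```

## The indicator and its inputs

The pipeline works on SDG indicator 3.7.1: among women of reproductive
age (WRA, 15–49 years), the share of those who want to avoid pregnancy
whose need is satisfied with a modern contraceptive method,

$$DS = \frac{\text{modern}}{\text{modern} + \text{traditional} + \text{unmet}},$$

where the three terms are proportions of WRA using a modern method,
using a traditional method, and with unmet need for family planning.
Total demand is the denominator; the women counted by
$\text{traditional} + \text{unmet}$ are exactly those with an *unmet
need for modern methods*. When total demand is zero the indicator is
defined as 0 (with a warning) rather than an error, so degenerate toy
inputs flow through.

The probabilistic input is a set of $S$ posterior trajectory samples per
country: joint time series of the triple (modern, traditional, unmet)
over 2019–2030, each triple on the simplex. `fpscenarios` consumes these
trajectories; it does not re-fit the Bayesian hierarchical model that
produces them, and it makes no adjustment for pandemic-era disruption
(the 2019 baseline is taken as is).

## Scenario construction

For country $c$ and trajectory $s$, the change in demand satisfied is
$\Delta_s = DS_s(T) - DS_s(B)$ with baseline year $B = 2019$ and target
year $T = 2030$. Over samples this yields the country's probability
distribution of the magnitude of change; computing it within each
trajectory keeps the calculation probabilistic throughout rather than
anchored to point estimates of the endpoints.

A scenario is a percentile $p$ of that change distribution:

$$DS^{(p)}_c(T) = \operatorname{clip}_{[0,1]}\!\left[
  \operatorname{median}_s DS_s(B) + Q_p(\Delta_1, \dots, \Delta_S)
\right].$$

Two scenarios are predefined: **current progress** at $p = 50$ (the
median change — what past trends make likely) and **accelerated
progress** at $p = 90$ (a change with a one-in-ten chance of being met or
exceeded). Percentiles beyond ~90 are best avoided because countries
with sparse survey data have wide intervals, making extreme percentiles
implausibly optimistic.

Two formula details were genuinely open design choices:

* **Anchoring at the median baseline.** The construction adds the change
  quantile to the median baseline level. This uses the full change
  distribution, reduces exactly to the median projection at $p = 50$,
  and keeps the scenario independent of any single trajectory's start
  value. Clips into $[0, 1]$ are logged per country.
* **Splitting median total demand.** Related indicators under a scenario
  need a consistent set of proportions. We carry the median of total
  demand at the target year, $\tilde D_c$, and split it by the scenario
  value: modern $= DS^{(p)}_c \tilde D_c$ and unmet-for-modern
  $= (1 - DS^{(p)}_c) \tilde D_c$. This preserves the accounting
  identity $DS = \text{users}/(\text{users} + \text{unmet})$ exactly. An
  alternative — conditioning the full joint trajectory set on the
  selected change quantile — would let total demand co-vary with the
  scenario; absent a stated rule for that conditioning we prefer the
  identity-preserving split, and flag it as a modelling choice. One
  consequence is that, country by country, users gained under
  acceleration equal unmet need lost.

**Percentile estimator.** Percentiles use linear interpolation between
order statistics with $p=0$ mapping to the minimum and $p=100$ to the
maximum (quantile "type 7", the default in most statistical software);
on an odd-length sample $p=50$ is the middle order statistic. The rule
is fixed and documented because scenario values at interpolated
percentiles depend on it.

## Accounting, impact and cost

Scenario proportions become absolute numbers by multiplying by the
country's WRA count (thousands) in the target year. Aggregates over
countries sum users, unmet need, pregnancies and costs; the aggregate
percentage is the ratio of sums $100\,\Sigma u/(\Sigma u + \Sigma m)$,
not the mean of country percentages, so the aggregate row obeys the same
identity as every country row.

Annual unintended pregnancies among women who want to avoid pregnancy:

$$UP = \sum_k \text{users} \cdot \text{mix}_k \cdot f_k
     + \text{unmet} \cdot r,$$

with a time-invariant method mix $\text{mix}_k$, age-adjusted annual
failure rates $f_k$ (per user-year, in $[0, 0.5)$), and a pregnancy rate
$r$ for women using traditional methods or no method. The default
$r = 0.448$ per woman-year is the median of the country-specific
distribution estimated for this group; a per-country rate column is
accepted instead, since published aggregate pregnancy totals are
consistent with country-specific rates rather than a uniform median.
Rates are annual probabilities applied to scenario-year counts; there
are no within-year dynamics, and women with no desire to avoid pregnancy
never enter.

Annual direct cost per user of method $k$ is the sum of three components
in base-year (2020) USD, each inflated to the target year by its own
rule, with multiplicative annual compounding throughout:

* **personnel** — country GDP-deflator rates for 2021–2024, then the
  arithmetic mean of those four rates for each year from 2025 on (the
  arithmetic mean is used where the rule says "the average"; the
  geometric mean was rejected for simplicity and the difference is
  second-order in the rates);
* **drugs & supplies** — one constant US inflation rate (the 2015–2019
  average) compounded from 2020;
* **commodity** — flat over 2020–2030, a conservative choice given that
  observed commodity prices fell over 2015–2019.

All factors equal 1 in 2020 and are nondecreasing in the target year for
nonnegative rates. Costs are nominal target-year USD with no
discounting, and deliberately exclude savings from averted pregnancies.
Cost components may be supplied per (country, method) or per method only
(broadcast to all countries).

## The synthetic-data generator

`generate_trajectories()` emulates the statistical structure the
analysis assumes, so the pipeline can be built and tested without the
real projection files. Each country's (modern, traditional, unmet)
composition (against the "no demand" remainder) is mapped to additive
log-ratio coordinates $z = \log(x_i / x_\text{rest})$ and evolved as a
random walk

$$z_{t+1} = z_t + d_c + \sigma_c \varepsilon_t, \qquad
  \varepsilon_t \sim N(0, R),$$

with drift $d_c$ on the modern coordinate only, a fixed innovation
correlation $R$ (modern gains trade off against traditional use and
unmet need), and a country-specific scale $\sigma_c$. The baseline year
carries the same spread, so 2019 uncertainty is represented. Mapping
back through the logistic transform guarantees the simplex constraint at
every year by construction — the property the real joint model satisfies
— without re-implementing that model.

Defaults define the study-scale conditions: 131 countries, 1000
trajectories, years 2019–2030, drift $\sim U(0, 0.03)$ per year on the
logit scale (a modest upward trend, up to roughly +8 percentage points
of coverage over 11 years at mid-scale), $\sigma_c \sim U(0.02, 0.10)$
(11-year uncertainty from ±2 to ±8 points — the width is a free knob
standing in for the data-richness mechanism that drives real interval
widths, which we do not emulate), baseline compositions drawn via
$DS_0 \sim U(0.20, 0.92)$, total demand $\sim U(0.30, 0.75)$ and a
traditional share of unserved demand $\sim U(0.10, 0.50)$ (spanning
low- to high-coverage settings), and WRA counts drawn log-uniformly on
100–60,000 thousand (small states through the most populous countries)
with smooth ±0.5–2%/year growth. Method-mix shares are normalized gamma
draws over 8 methods; failure rates $U(0.002, 0.15)$ span long-acting
through short-term methods; cost components are sized so a typical total
cost lands at a few USD per user-year; country inflation rates are
$U(0.01, 0.12)$ and the US rate $U(0.01, 0.04)$. Country labels are
synthetic (`C001`, …) and one global seed fans out to independent
per-generator substreams, so adding a generator perturbs nothing else.

What passing tests on synthetic data do and do not show: they verify the
scenario arithmetic, the accounting identities, percentile monotonicity,
inflation compounding and end-to-end determinism under realistic input
*structure*; they do not certify agreement with published country
figures, because the generator makes no attempt to mimic real countries'
values, survey-driven uncertainty widths, or the correlation between
coverage levels and population size.

## Numerical choices and degenerate inputs

* Simplex validation tolerates $10^{-9}$ of numerical slack; quantile
  comparisons in tests use $10^{-12}$.
* Zero total demand yields $DS = 0$ with a warning; zero or missing
  populations, mismatched country sets (reported as a symmetric
  difference), and mix methods without failure rates or costs (reported
  by name) are errors.
* With all trajectories identical, every percentile gives the same
  scenario — the degenerate-noise limit used as a test oracle.
* Report tables round to 3 significant figures for display only;
  differences are computed on unrounded values before any rounding.

## Problem sizes used in the tests

Unit and property tests run at small scale (2–40 countries, 10–300
samples). Calibration checks use 2000 samples per country — the median
scenario recovers a known drift-implied target value within three
Monte-Carlo standard errors estimated from replicate generations — and
the study-scale run in `scripts/acceptance.R` uses the full default
configuration (131 countries × 1000 trajectories) including the CSV
round trip.

## Interface note

This is an analysis package: the pipeline surface is R functions
(`run_pipeline()`, `write_input_bundle()`, `count_below_threshold()`)
driven by a YAML run configuration, plus `scripts/acceptance.R` for the
scripted end-to-end run; no standalone command-line binary is shipped.

## Known limitations

* The scenario-level split of median total demand cannot represent
  scenario-dependent total demand (see above).
* Point scenarios only: no uncertainty intervals around scenario
  outputs.
* The uniform pregnancy-rate default understates country heterogeneity;
  supply a `country,pregnancy_rate` table where country rates exist.
* No cost savings from averted pregnancies, no discounting, no
  sub-national or age-disaggregated accounting, and no modelling of
  shocks such as epidemics.
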