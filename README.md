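# fpscenarios

Country-specific target setting for contraceptive coverage from
probabilistic projections.

## The problem

SDG indicator 3.7.1 — the proportion of women of reproductive age (15–49)
whose need for family planning is satisfied with modern contraceptive
methods — is tracked per country, but targets for it are often set as one
fixed level for every country, ignoring wildly different starting points
and historical rates of progress. When probabilistic projections of the
indicator are available (posterior trajectory samples of modern use,
traditional use and unmet need, jointly projected to 2030), the
uncertainty itself can define realistic, country-specific targets.

`fpscenarios` implements that pipeline for analysts working with such
projections:

1. **Scenario construction.** For each country, the per-trajectory change
   in demand satisfied between a baseline year (2019) and a target year
   (2030) gives a probability distribution of the magnitude of change.
   With *DS* = modern / (modern + traditional + unmet), the scenario value
   is

   *DS*<sub>target</sub> = clip₍₀,₁₎ [ median(*DS*<sub>baseline</sub>) + *Q*<sub>p</sub>(ΔDS) ],

   where *Q*<sub>p</sub> is the p-th percentile (linear interpolation
   between order statistics, the "type 7" rule). p = 50 defines the
   **current progress** scenario (what past trends make likely); p = 90
   defines **accelerated progress** (a change with a one-in-ten chance of
   being met or exceeded — ambitious but not extreme).
2. **Accounting.** Scenario proportions × women of reproductive age give
   absolute numbers of modern-method users and of women with unmet need
   for modern methods (thousands).
3. **Impact.** Annual unintended pregnancies
   = Σ<sub>k</sub> users · mix<sub>k</sub> · failure<sub>k</sub> + unmet · 0.448,
   using a constant method mix, per-method annual failure rates, and a
   pregnancy rate of 44.8%/year for women using traditional methods or no
   method.
4. **Cost.** Annual direct cost per user = personnel + drugs & supplies +
   commodity, each inflated from its 2020 base with its own rule
   (country GDP-deflator rates for personnel; a constant US rate for
   drugs & supplies; commodities flat), then totalled over users.
5. **Comparison.** Countries are aggregated (the aggregate percentage is
   the ratio of sums, not a mean of ratios) into a two-scenario table with
   an accelerated-minus-current difference column.

A synthetic-data module generates all inputs with the statistical
structure the analysis assumes — joint simplex-constrained logit-scale
random-walk trajectories with country-varying uncertainty — so the whole
pipeline runs without any external download.

## Worked example

```r
library(fpscenarios)

cfg <- simulation_config(n_countries = 10, n_samples = 500, seed = 2024)
bundle <- write_input_bundle(cfg, "demo")     # CSVs + config.yml
res <- run_pipeline(bundle$config, quiet = TRUE)
print(res$comparison)
```

```
Quantity                                         current  accelerated  difference
---------------------------------------------------------------------------------
% of demand satisfied by modern methods             78.3         81.5        3.23
Women using modern methods (000s)                 11,000       11,400         453
Women with unmet need for modern methods (000s)    3,050        2,600        -453
Unintended pregnancies (000s)                      2,390        2,220        -161
Annual total direct costs ($ 000s)                67,200       69,900       2,730
```

Reading the table: if these ten synthetic countries continue on their
current pace, 78.3% of women who want to avoid pregnancy would be using a
modern method in 2030; pushing every country to the 90th percentile of its
own change distribution lifts that to 81.5%, moving 453,000 women from
unmet need into modern use, averting 161,000 unintended pregnancies a
year, and costing an extra $2.7 million a year in direct service costs.
(Users gained equals unmet need lost because both scenarios share the
median total-demand projection.) Country-level rows are in
`res$country_results`, and

```r
count_below_threshold(res$country_results, 75, "accelerated")
#> [1] 6
```

counts the countries still under 75% coverage even when accelerated.

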