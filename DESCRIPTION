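Package: fpscenarios
Title: Percentile-Based Scenario Targets for Contraceptive Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs country-specific "current progress" and "accelerated
    progress" scenarios for the demand-satisfied-with-modern-methods
    indicator (SDG 3.7.1) from percentiles of each country's probability
    distribution of change between a baseline and a target year, computed
    over posterior trajectory samples of modern use, traditional use and
    unmet need for family planning. Converts scenario proportions into
    absolute numbers of modern-method users and women with unmet need for
    modern methods, computes annual unintended pregnancies from a method
    mix and per-method failure rates, projects annual direct costs under
    component-specific inflation rules, and aggregates countries into a
    two-scenario comparison table. Includes a synthetic-data generator
    that emulates the statistical structure of the probabilistic inputs
    (simplex-constrained joint trajectories with country-varying
    uncertainty) so the pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
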