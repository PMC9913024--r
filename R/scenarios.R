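#' Demand for family planning satisfied with modern methods
#'
#' Computes the SDG 3.7.1 indicator: the proportion of women of
#' reproductive age who want to avoid pregnancy (total demand = any
#' contraceptive use + unmet need) whose need is met with a modern method,
#'
#' \deqn{DS = modern / (modern + traditional + unmet).}
#'
#' Zero total demand returns 0 with a warning, so degenerate all-zero
#' inputs flow through rather than erroring.
#'
#' @param modern,traditional,unmet Proportions of WRA in \[0, 1\] with
#'   componentwise sum at most 1. Vectorized.
#' @return The demand-satisfied proportion(s), same length as the inputs.
#' @examples
#' demand_satisfied(0.30, 0.10, 0.10)  # 0.6
#' @export
demand_satisfied <- function(modern, traditional, unmet) {
  total <- modern + traditional + unmet
  if (any(!is.finite(total))) {
    abort("Non-finite proportions passed to demand_satisfied().",
          class = "fps_input_error")
  }
  zero <- total == 0
  if (any(zero)) {
    warn("Zero total demand encountered; demand satisfied defined as 0.")
  }
  out <- numeric(length(total))
  out[!zero] <- modern[!zero] / total[!zero]
  out
}

#' Linear-interpolation percentile of a sample
#'
#' The percentile estimator used throughout the scenario construction:
#' linear interpolation between order statistics with p = 0 mapping to the
#' minimum and p = 100 to the maximum (the common "type 7" scheme, the
#' default in most statistical software). On an odd-length sample p = 50
#' returns the middle order statistic.
#'
#' @param values Numeric vector, non-empty, finite.
#' @param p Percentile in \[0, 100\].
#' @return A single number.
#' @examples
#' fp_quantile(c(1, 2, 3), 50)   # 2
#' fp_quantile(0:10, 90)         # 9
#' @export
fp_quantile <- function(values, p) {
  if (length(values) == 0L) {
    abort("Cannot take a percentile of an empty sample.",
          class = "fps_input_error")
  }
  if (any(!is.finite(values))) {
    abort("Percentile input contains non-finite values.",
          class = "fps_input_error")
  }
  assert_number(p, "p", lower = 0, upper = 100)
  unname(quantile(values, probs = p / 100, type = 7, names = FALSE))
}

#' Define a progress scenario
#'
#' A scenario is a named percentile of the country-specific probability
#' distribution of change in demand satisfied between a baseline and a
#' target year. The defaults mirror the two published scenarios: "current
#' progress" takes the median (50th percentile) of each country's change
#' distribution — what is likely to happen on past trends — and
#' "accelerated progress" the 90th percentile, a level of change with a
#' one-in-ten chance of being met or exceeded.
#'
#' @param name Scenario label, e.g. `"current"` or `"accelerated"`.
#' @param percentile Percentile of the change distribution, in (0, 100).
#' @param baseline_year,target_year Calendar years; the baseline must
#'   precede the target and both must be covered by the trajectory set the
#'   scenario is applied to.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(name, percentile, baseline_year = 2019L,
                          target_year = 2030L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  assert_number(percentile, "percentile")
  if (percentile <= 0 || percentile >= 100) {
    abort("`percentile` must lie strictly between 0 and 100.",
          class = "fps_config_error")
  }
  baseline_year <- assert_count(baseline_year, "baseline_year")
  target_year <- assert_count(target_year, "target_year")
  if (baseline_year >= target_year) {
    abort("`baseline_year` must precede `target_year`.",
          class = "fps_config_error")
  }
  structure(list(name = name, percentile = percentile,
                 baseline_year = baseline_year, target_year = target_year),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> \"%s\": percentile %g of change %d-%d\n",
              x$name, x$percentile, x$baseline_year, x$target_year))
  invisible(x)
}

# Slice the (sample x year-pair) demand-satisfied values for one country.
country_index <- function(traj, country) {
  i <- match(country, traj$countries)
  if (is.na(i)) {
    abort(sprintf("Country %s not present in trajectory set.", country),
          class = "fps_input_error")
  }
  i
}

year_index <- function(traj, year) {
  j <- match(year, traj$years)
  if (is.na(j)) {
    abort(sprintf("Year %d not present in trajectory set.", year),
          class = "fps_input_error")
  }
  j
}

ds_samples <- function(traj, ci, yi) {
  demand_satisfied(traj$modern[ci, , yi],
                   traj$traditional[ci, , yi],
                   traj$unmet[ci, , yi])
}

#' Per-trajectory distribution of change in demand satisfied
#'
#' For one country, returns the length-S vector whose element s is the
#' demand-satisfied proportion at the target year minus that at the
#' baseline year, computed within posterior trajectory s. This is the
#' country-specific probability distribution of the magnitude of change
#' between the baseline and target years; taking it trajectory-by-
#' trajectory keeps the probabilistic calculation independent of the
#' start and end point estimates.
#'
#' @param traj A `trajectory_set`.
#' @param country A country identifier present in `traj`.
#' @param spec A [scenario_spec()] (supplies baseline and target years).
#' @return Numeric vector of length `traj$n_samples`.
#' @export
change_distribution <- function(traj, country, spec) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(spec, "scenario_spec"))
  ci <- country_index(traj, country)
  yb <- year_index(traj, spec$baseline_year)
  yt <- year_index(traj, spec$target_year)
  ds_samples(traj, ci, yt) - ds_samples(traj, ci, yb)
}

#' Scenario proportions for one country at the target year
#'
#' Builds the country's scenario value of demand satisfied at the target
#' year and the related indicator proportions:
#'
#' \enumerate{
#'   \item `demand_satisfied` = clip to \[0, 1\] of: median over samples of
#'     baseline demand satisfied + the scenario percentile of the
#'     per-trajectory change distribution ([change_distribution()]);
#'   \item `total_demand` = median over samples of total demand
#'     (modern + traditional + unmet) at the target year;
#'   \item `modern` = `demand_satisfied` x `total_demand`, the proportion
#'     of WRA using modern methods;
#'   \item `trad_plus_unmet` = `total_demand` - `modern`, the proportion of
#'     WRA with an unmet need for modern methods (traditional users plus
#'     women with unmet need for any method).
#' }
#'
#' Splitting the median total demand by the scenario demand-satisfied
#' value preserves the accounting identity
#' `demand_satisfied = modern / total_demand` exactly. At percentile 50
#' the construction reduces to the median projection.
#'
#' @inheritParams change_distribution
#' @return A one-row tibble with columns `country`, `scenario`,
#'   `percentile`, `target_year`, `demand_satisfied`, `modern`,
#'   `trad_plus_unmet`, `total_demand`, `clipped` (whether the \[0, 1\]
#'   clip was triggered).
#' @export
scenario_proportions <- function(traj, country, spec) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(spec, "scenario_spec"))
  ci <- country_index(traj, country)
  yb <- year_index(traj, spec$baseline_year)
  yt <- year_index(traj, spec$target_year)

  ds_base <- ds_samples(traj, ci, yb)
  change <- ds_samples(traj, ci, yt) - ds_base
  ds_raw <- fp_quantile(ds_base, 50) + fp_quantile(change, spec$percentile)
  ds <- min(max(ds_raw, 0), 1)

  total_target <- traj$modern[ci, , yt] + traj$traditional[ci, , yt] +
    traj$unmet[ci, , yt]
  total_demand <- fp_quantile(total_target, 50)
  modern <- ds * total_demand

  tibble::tibble(
    country = traj$countries[ci],
    scenario = spec$name,
    percentile = spec$percentile,
    target_year = spec$target_year,
    demand_satisfied = ds,
    modern = modern,
    trad_plus_unmet = total_demand - modern,
    total_demand = total_demand,
    clipped = ds_raw < 0 || ds_raw > 1
  )
}

#' Scenario proportions for every country
#'
#' @inheritParams change_distribution
#' @return A tibble with one row per country; see [scenario_proportions()].
#' @export
scenario_proportions_all <- function(traj, spec) {
  stopifnot(inherits(traj, "trajectory_set"))
  dplyr::bind_rows(lapply(traj$countries, function(cc) {
    scenario_proportions(traj, cc, spec)
  }))
}
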