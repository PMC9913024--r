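#' Build a run configuration
#'
#' Collects the input paths, scenario definitions and scalar parameters
#' that drive [run_pipeline()]. Defaults mirror the published analysis
#' setup: a 2019 baseline, a 2030 target, a "current progress" scenario at
#' the 50th percentile of each country's change distribution and an
#' "accelerated progress" scenario at the 90th, a non-user pregnancy rate
#' of 0.448, and 3-significant-figure report rounding.
#'
#' @param trajectories,population,method_mix,failure_rates,costs,inflation
#'   Paths to the input CSVs (dialects documented on their readers).
#' @param us_rate US annual inflation rate applied to drugs-and-supplies
#'   costs.
#' @param pregnancy_rate Scalar non-user pregnancy rate, or the path to a
#'   `country,pregnancy_rate` CSV.
#' @param scenarios List of [scenario_spec()] objects, or of
#'   `list(name =, percentile =)` pairs; at least one.
#' @param baseline_year,target_year Analysis years.
#' @param output_dir Where [run_pipeline()] writes its outputs (`NULL` to
#'   skip writing).
#' @param report_sigfigs Significant figures for the rendered text table.
#' @return A `run_config` object.
#' @export
run_config <- function(trajectories, population, method_mix, failure_rates,
                       costs, inflation, us_rate,
                       pregnancy_rate = 0.448,
                       scenarios = list(
                         list(name = "current", percentile = 50),
                         list(name = "accelerated", percentile = 90)),
                       baseline_year = 2019L, target_year = 2030L,
                       output_dir = NULL, report_sigfigs = 3L) {
  if (length(scenarios) < 1L) {
    abort("At least one scenario is required.", class = "fps_config_error")
  }
  specs <- lapply(scenarios, function(s) {
    scenario_spec(s$name, s$percentile, baseline_year, target_year)
  })
  assert_number(us_rate, "us_rate", lower = 0)
  structure(list(
    paths = list(trajectories = trajectories, population = population,
                 method_mix = method_mix, failure_rates = failure_rates,
                 costs = costs, inflation = inflation),
    us_rate = us_rate, pregnancy_rate = pregnancy_rate,
    scenarios = specs,
    baseline_year = as.integer(baseline_year),
    target_year = as.integer(target_year),
    output_dir = output_dir,
    report_sigfigs = as.integer(report_sigfigs)),
    class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; relative input paths are
#' resolved against the directory containing the file.
#' [write_input_bundle()] emits a compatible `config.yml`.
#'
#' @param path Path to a YAML run configuration.
#' @param output_dir Optional output directory overriding the file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path, output_dir = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "fps_input_error")
  }
  cfg <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.numeric(p)) return(p)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  req <- c("trajectories", "population", "method_mix", "failure_rates",
           "costs", "inflation", "us_rate")
  missing_keys <- setdiff(req, names(cfg))
  if (length(missing_keys) > 0L) {
    abort(sprintf("Run config is missing key(s): %s.",
                  paste(missing_keys, collapse = ", ")),
          class = "fps_config_error")
  }
  run_config(
    trajectories = resolve(cfg$trajectories),
    population = resolve(cfg$population),
    method_mix = resolve(cfg$method_mix),
    failure_rates = resolve(cfg$failure_rates),
    costs = resolve(cfg$costs),
    inflation = resolve(cfg$inflation),
    us_rate = cfg$us_rate,
    pregnancy_rate = resolve(cfg$pregnancy_rate %||% 0.448),
    scenarios = cfg$scenarios %||% list(
      list(name = "current", percentile = 50),
      list(name = "accelerated", percentile = 90)),
    baseline_year = cfg$baseline_year %||% 2019L,
    target_year = cfg$target_year %||% 2030L,
    output_dir = output_dir %||% cfg$output_dir,
    report_sigfigs = cfg$report_sigfigs %||% 3L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Country-set consistency across inputs: error lists the symmetric
# difference relative to the trajectory set.
check_country_sets <- function(traj_countries, other, what) {
  sdiff <- c(setdiff(traj_countries, other), setdiff(other, traj_countries))
  if (length(sdiff) > 0L) {
    abort(sprintf(
      "Country sets differ between trajectories and %s; symmetric difference: %s.",
      what, paste(sort(unique(sdiff)), collapse = ", ")),
      class = "fps_input_error")
  }
}

#' Run the scenario pipeline end to end
#'
#' Reads every input named in the configuration, computes for each
#' scenario and country the target-year proportions
#' ([scenario_proportions()]), absolute numbers ([absolute_numbers()]),
#' annual unintended pregnancies ([unintended_pregnancies()]) and annual
#' total direct costs ([total_cost()] under the component inflation
#' rules), then aggregates all countries and lays the first two scenarios
#' out as the comparison table. Deterministic given the inputs.
#'
#' If `output_dir` is set, writes `country_results.csv` (the machine twin
#' of a country-level appendix table, one row per country and scenario),
#' `comparison.csv` and a rendered `comparison.txt`.
#'
#' @param config A `run_config` (or the path to a YAML config file).
#' @param quiet Suppress the per-country clip log messages.
#' @return An `fp_run` list: `comparison` (a `scenario_comparison`),
#'   `aggregates`, `country_results`, `clip_log`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  traj <- read_trajectories(config$paths$trajectories)
  pop <- read_population(config$paths$population)
  mix <- read_method_mix(config$paths$method_mix)
  failures <- read_failure_rates(config$paths$failure_rates)
  cost_components <- read_cost_components(config$paths$costs)
  inflation <- read_inflation(config$paths$inflation)
  pregnancy_rate <- config$pregnancy_rate
  if (is.character(pregnancy_rate)) {
    pregnancy_rate <- read_pregnancy_rates(pregnancy_rate)
  }

  check_country_sets(traj$countries,
                     unique(pop$country[pop$year == config$target_year]),
                     "population (target year)")
  check_country_sets(traj$countries, unique(inflation$country), "inflation")
  if ("country" %in% names(cost_components)) {
    check_country_sets(traj$countries, unique(cost_components$country),
                       "cost components")
  }
  mismatched <- c(setdiff(mix$method, failures$method),
                  setdiff(mix$method, unique(cost_components$method)))
  if (length(mismatched) > 0L) {
    abort(sprintf("Method keys misaligned across inputs: %s.",
                  paste(sort(unique(mismatched)), collapse = ", ")),
          class = "fps_input_error")
  }

  # per-country per-user method costs at the target year
  cost_by_country <- function(cc) {
    comp <- if ("country" %in% names(cost_components)) {
      cost_components[cost_components$country == cc, ]
    } else {
      cost_components
    }
    rates <- as.numeric(inflation[inflation$country == cc,
                                  paste0("rate_", 2021:2024)])
    stats::setNames(
      cost_per_user(comp$personnel, comp$drugs_supplies, comp$commodity,
                    rates, config$us_rate, config$target_year),
      comp$method)
  }
  per_user_costs <- lapply(stats::setNames(nm = traj$countries),
                           cost_by_country)

  results <- dplyr::bind_rows(lapply(config$scenarios, function(spec) {
    props <- scenario_proportions_all(traj, spec)
    rows <- absolute_numbers(props, pop)
    rows$unintended_pregnancies_thousands <- unintended_pregnancies(
      rows$users_modern_thousands, rows$unmet_modern_thousands,
      mix, failures, pregnancy_rate, country = rows$country)
    rows$total_cost_usd_thousands <- vapply(seq_len(nrow(rows)), function(i) {
      total_cost(rows$users_modern_thousands[i], mix,
                 per_user_costs[[rows$country[i]]])
    }, numeric(1L))
    rows
  }))

  clip_log <- dplyr::filter(results, .data$clipped)
  if (!quiet) {
    for (i in seq_len(nrow(clip_log))) {
      message(sprintf(
        "clip: country %s scenario %s demand satisfied clipped into [0, 1]",
        clip_log$country[i], clip_log$scenario[i]))
    }
  }

  aggregates <- aggregate_results(results)
  scenario_names <- vapply(config$scenarios, `[[`, character(1L), "name")
  comparison <- if (length(scenario_names) >= 2L) {
    compare_scenarios(results, scenarios = scenario_names[1:2])
  } else {
    NULL
  }

  country_results <- dplyr::select(
    results, "country", "scenario", "demand_satisfied",
    "users_modern_thousands", "unmet_modern_thousands",
    "unintended_pregnancies_thousands", "total_cost_usd_thousands")

  out <- structure(list(comparison = comparison, aggregates = aggregates,
                        country_results = country_results,
                        clip_log = clip_log, config = config),
                   class = "fp_run")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(country_results,
                     file.path(config$output_dir, "country_results.csv"))
    if (!is.null(comparison)) {
      readr::write_csv(comparison,
                       file.path(config$output_dir, "comparison.csv"))
      writeLines(render_comparison(comparison, config$report_sigfigs),
                 file.path(config$output_dir, "comparison.txt"))
    }
  }
  out
}

#' @export
print.fp_run <- function(x, ...) {
  cat(sprintf("<fp_run> %d countries, %d scenario(s)\n",
              length(unique(x$country_results$country)),
              length(unique(x$country_results$scenario))))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Count countries below a coverage threshold
#'
#' Counts countries whose demand satisfied with modern methods falls
#' strictly below a threshold (in percent) — e.g. how many countries stay
#' under the 75% level, a proposed common target, even under accelerated
#' progress.
#'
#' @param country_results Country-level results (one scenario, or use
#'   `scenario` to select one) with columns `country`,
#'   `demand_satisfied` (proportion).
#' @param threshold Percent threshold (default 75).
#' @param scenario Optional scenario label to filter on.
#' @return Integer count of countries.
#' @export
count_below_threshold <- function(country_results, threshold = 75,
                                  scenario = NULL) {
  stopifnot(is.data.frame(country_results))
  assert_number(threshold, "threshold", lower = 0, upper = 100)
  rows <- country_results
  if (!is.null(scenario)) {
    rows <- dplyr::filter(rows, .data$scenario == !!scenario)
  }
  if (anyDuplicated(rows$country) > 0L) {
    abort("Rows for more than one scenario; pass `scenario` to select one.",
          class = "fps_input_error")
  }
  sum(100 * rows$demand_satisfied < threshold)
}
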