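#' Configuration for the synthetic input generator
#'
#' The generator emulates the statistical structure of the probabilistic
#' family-planning projections the pipeline consumes: joint,
#' simplex-constrained posterior trajectories of modern use, traditional
#' use and unmet need, with country-specific drift and country-varying
#' uncertainty width (countries with less survey data have wider
#' intervals; here the width is a free knob drawn uniformly from
#' `noise_range`, not an emulation of the data-driven mechanism).
#'
#' Defaults describe a study-scale setup: 131 low- and middle-income
#' countries observed 2019-2030. Country labels are synthetic
#' (`"C001"`, ...); no attempt is made to mimic real countries' values.
#'
#' @param n_countries Number of countries (default 131).
#' @param n_samples Posterior trajectories per country (default 1000,
#'   minimum 2).
#' @param years Inclusive integer year range (default 2019:2030).
#' @param seed Integer seed; a single global seed fans out to independent
#'   per-generator substreams, so adding a generator does not perturb the
#'   others.
#' @param drift_range Pair: per-year drift on the logit-scale modern-use
#'   coordinate, drawn uniformly per country (default `c(0, 0.03)`,
#'   a modest upward trend).
#' @param noise_range Pair: per-year logit-scale innovation standard
#'   deviation, drawn uniformly per country (default `c(0.02, 0.10)`);
#'   the lower bound must be positive so every country carries nonzero
#'   uncertainty.
#' @param population_range Pair: bounds (in thousands) for women of
#'   reproductive age per country, drawn log-uniformly (default
#'   `c(100, 60000)`, spanning small states to the most populous LMICs).
#' @param n_methods Number of modern methods in the mix (default 8).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_countries = 131L, n_samples = 1000L,
                              years = 2019:2030, seed = 1L,
                              drift_range = c(0, 0.03),
                              noise_range = c(0.02, 0.10),
                              population_range = c(100, 60000),
                              n_methods = 8L) {
  n_countries <- assert_count(n_countries, "n_countries", min = 1L)
  n_samples <- assert_count(n_samples, "n_samples", min = 2L)
  seed <- assert_count(seed, "seed", min = -.Machine$integer.max)
  n_methods <- assert_count(n_methods, "n_methods", min = 1L)
  if (!is.numeric(years) || length(years) < 2L ||
      any(diff(years) != 1L)) {
    abort("`years` must be an inclusive run of at least 2 calendar years.",
          class = "fps_config_error")
  }
  for (nm in c("drift_range", "noise_range", "population_range")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) ||
        v[1L] > v[2L]) {
      abort(sprintf("`%s` must be a finite non-decreasing pair.", nm),
            class = "fps_config_error")
    }
  }
  if (noise_range[1L] <= 0) {
    abort("`noise_range` lower bound must be > 0: every country has nonzero uncertainty.",
          class = "fps_config_error")
  }
  if (population_range[1L] <= 0) {
    abort("`population_range` must be strictly positive.",
          class = "fps_config_error")
  }
  structure(list(n_countries = n_countries, n_samples = n_samples,
                 years = as.integer(years), seed = seed,
                 drift_range = as.numeric(drift_range),
                 noise_range = as.numeric(noise_range),
                 population_range = as.numeric(population_range),
                 n_methods = n_methods),
            class = "simulation_config")
}

# Independent substream seed for generator `k` under global seed `seed`.
substream_seed <- function(seed, k) {
  as.integer((abs(as.double(seed)) * 48271 + k * 1000003) %% 2147483647)
}

country_labels <- function(n) sprintf("C%03d", seq_len(n))

# Innovation correlation across the three additive-log-ratio coordinates
# (modern, traditional, unmet): modern gains tend to come at the expense
# of traditional use and unmet need, which co-move weakly.
alr_innovation_chol <- function() {
  R <- matrix(c(1, -0.2, -0.4,
                -0.2, 1, 0.3,
                -0.4, 0.3, 1), nrow = 3L, byrow = TRUE)
  chol(R)
}

# Draw a country's baseline (modern, traditional, unmet) composition from
# realistic LMIC-like marginals: baseline demand satisfied spread widely,
# total demand moderate, and a traditional-method share of the unserved
# demand. Returns a 3-column matrix.
draw_baseline_composition <- function(n) {
  ds0 <- runif(n, 0.20, 0.92)      # baseline demand satisfied
  total <- runif(n, 0.30, 0.75)    # total demand among WRA
  phi <- runif(n, 0.10, 0.50)      # traditional share of unserved demand
  modern <- ds0 * total
  rest <- (1 - ds0) * total
  cbind(modern = modern, traditional = phi * rest,
        unmet = (1 - phi) * rest)
}

#' Generate synthetic posterior trajectories
#'
#' Simulates, per country, `n_samples` joint trajectories of (modern,
#' traditional, unmet) proportions as an additive logistic-normal random
#' walk: the three-part composition (against the "no demand" remainder) is
#' mapped to additive-log-ratio (alr) coordinates, given a country-specific
#' per-year drift on the modern coordinate and correlated Gaussian
#' innovations with country-specific scale, then mapped back to the
#' simplex. The construction guarantees the simplex constraint at every
#' year without re-implementing the hierarchical projection model the real
#' inputs come from. Baseline-year values carry the same country-specific
#' spread, so baseline uncertainty is represented too.
#'
#' @param config A [simulation_config()].
#' @return A `trajectory_set`. The attribute `"params"` holds the per-
#'   country generating parameters (baseline composition, drift, noise
#'   scale) used by calibration checks.
#' @export
generate_trajectories <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(substream_seed(config$seed, 1L))
  nc <- config$n_countries; ns <- config$n_samples
  years <- config$years; ny <- length(years)
  countries <- country_labels(nc)

  base <- draw_baseline_composition(nc)
  sigma <- runif(nc, config$noise_range[1L], config$noise_range[2L])
  drift <- runif(nc, config$drift_range[1L], config$drift_range[2L])
  L <- alr_innovation_chol()

  dn <- list(countries, NULL, as.character(years))
  modern <- array(NA_real_, c(nc, ns, ny), dimnames = dn)
  traditional <- modern
  unmet <- modern

  for (i in seq_len(nc)) {
    rest0 <- 1 - sum(base[i, ])
    mu <- log(base[i, ] / rest0)                  # alr coordinates
    d <- c(drift[i], 0, 0)
    z <- matrix(mu, nrow = ns, ncol = 3L, byrow = TRUE) +
      sigma[i] * (matrix(rnorm(ns * 3L), ns, 3L) %*% L)
    for (j in seq_len(ny)) {
      if (j > 1L) {
        z <- z + matrix(d, nrow = ns, ncol = 3L, byrow = TRUE) +
          sigma[i] * (matrix(rnorm(ns * 3L), ns, 3L) %*% L)
      }
      e <- exp(z)
      x <- e / (1 + rowSums(e))
      modern[i, , j] <- x[, 1L]
      traditional[i, , j] <- x[, 2L]
      unmet[i, , j] <- x[, 3L]
    }
  }

  traj <- trajectory_set(modern, traditional, unmet)
  attr(traj, "params") <- tibble::tibble(
    country = countries,
    modern0 = base[, "modern"], traditional0 = base[, "traditional"],
    unmet0 = base[, "unmet"], drift = drift, sigma = sigma)
  traj
}

#' Generate a synthetic population table
#'
#' Counts of women of reproductive age (thousands) per country-year,
#' strictly positive and smoothly varying: a log-uniform baseline within
#' `population_range` grows at a country-specific annual rate (between
#' -0.5\% and +2\%), with the end point clamped back into the range so a
#' degenerate range yields exactly constant populations.
#'
#' @param config A [simulation_config()].
#' @return A tibble `country,year,wra_thousands`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(substream_seed(config$seed, 2L))
  nc <- config$n_countries
  years <- config$years; ny <- length(years)
  lo <- config$population_range[1L]; hi <- config$population_range[2L]
  p_start <- if (lo == hi) rep(lo, nc) else exp(runif(nc, log(lo), log(hi)))
  growth <- runif(nc, -0.005, 0.02)
  p_end <- pmin(pmax(p_start * (1 + growth)^(ny - 1L), lo), hi)
  # geometric interpolation start -> end keeps counts positive and smooth
  frac <- (seq_len(ny) - 1L) / (ny - 1L)
  counts <- p_start * (p_end / p_start)^matrix(frac, nc, ny, byrow = TRUE)
  tibble::tibble(
    country = rep(country_labels(nc), each = ny),
    year = rep(years, times = nc),
    wra_thousands = as.vector(t(counts))
  )
}

#' Generate a synthetic method mix, failure rates and cost components
#'
#' The method mix (shares of modern users by method, time-invariant) is a
#' normalized Dirichlet-type draw; annual failure rates are uniform on
#' \[0.002, 0.15\], spanning long-acting methods through short-term
#' barrier methods; per-(country, method) cost components are uniform
#' draws sized so a typical total direct cost lands at a few USD per
#' user-year (personnel 0.5-3, drugs & supplies 0.3-2, commodity 0.2-2.5,
#' base-year USD).
#'
#' @param config A [simulation_config()].
#' @return A list with elements `mix` (`method,share`), `failure_rates`
#'   (`method,annual_failure_rate`) and `costs`
#'   (`country,method,personnel,drugs_supplies,commodity`).
#' @export
generate_method_inputs <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(substream_seed(config$seed, 3L))
  nm <- config$n_methods
  methods <- paste0("method_", seq_len(nm))
  raw <- rgamma(nm, shape = 2)
  mix <- tibble::tibble(method = methods, share = raw / sum(raw))
  failure_rates <- tibble::tibble(
    method = methods,
    annual_failure_rate = runif(nm, 0.002, 0.15))
  nc <- config$n_countries
  countries <- country_labels(nc)
  costs <- tibble::tibble(
    country = rep(countries, each = nm),
    method = rep(methods, times = nc),
    personnel = runif(nc * nm, 0.5, 3),
    drugs_supplies = runif(nc * nm, 0.3, 2),
    commodity = runif(nc * nm, 0.2, 2.5))
  list(mix = mix, failure_rates = failure_rates, costs = costs)
}

#' Generate synthetic inflation inputs
#'
#' Country GDP-deflator growth rates for 2021-2024 drawn uniformly on
#' \[0.01, 0.12\] (within the plausible band (-0.05, 0.25)), plus a single
#' US inflation rate on \[0.01, 0.04\] standing for the 2015-2019 average
#' applied to drugs-and-supplies costs.
#'
#' @param config A [simulation_config()].
#' @return A list with `rates` (tibble
#'   `country,rate_2021,rate_2022,rate_2023,rate_2024`) and `us_rate`
#'   (scalar).
#' @export
generate_inflation_inputs <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(substream_seed(config$seed, 4L))
  nc <- config$n_countries
  rates <- matrix(runif(nc * 4L, 0.01, 0.12), nrow = nc)
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(rates), paste0("rate_", 2021:2024)))
  out <- tibble::add_column(out, country = country_labels(nc),
                            .before = 1L)
  list(rates = out, us_rate = runif(1L, 0.01, 0.04))
}

#' Write a complete self-consistent synthetic input bundle
#'
#' Generates every pipeline input under one configuration and writes them
#' as the pipeline's CSV dialects into a directory, together with a
#' `config.yml` run configuration pointing at the files, so the whole
#' analysis can be run from the bundle alone.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths (plus the
#'   config path).
#' @export
write_input_bundle <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traj <- generate_trajectories(config)
  pop <- generate_population(config)
  mi <- generate_method_inputs(config)
  infl <- generate_inflation_inputs(config)

  paths <- list(
    trajectories = file.path(dir, "trajectories.csv"),
    population = file.path(dir, "population.csv"),
    method_mix = file.path(dir, "method_mix.csv"),
    failure_rates = file.path(dir, "failure_rates.csv"),
    costs = file.path(dir, "cost_components.csv"),
    inflation = file.path(dir, "inflation.csv"))
  write_trajectories(traj, paths$trajectories)
  readr::write_csv(pop, paths$population)
  readr::write_csv(mi$mix, paths$method_mix)
  readr::write_csv(mi$failure_rates, paths$failure_rates)
  readr::write_csv(mi$costs, paths$costs)
  readr::write_csv(infl$rates, paths$inflation)

  cfg <- list(
    trajectories = basename(paths$trajectories),
    population = basename(paths$population),
    method_mix = basename(paths$method_mix),
    failure_rates = basename(paths$failure_rates),
    costs = basename(paths$costs),
    inflation = basename(paths$inflation),
    us_rate = infl$us_rate,
    pregnancy_rate = 0.448,
    baseline_year = min(config$years),
    target_year = max(config$years),
    scenarios = list(list(name = "current", percentile = 50),
                     list(name = "accelerated", percentile = 90)))
  config_path <- file.path(dir, "config.yml")
  yaml::write_yaml(cfg, config_path)
  invisible(c(paths, list(config = config_path)))
}
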