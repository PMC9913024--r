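# Inflation of base-year (2020) cost components to a target year. Each
# component follows its own rule; all factors use multiplicative annual
# compounding from the 2020 base.

check_cost_year <- function(target_year) {
  target_year <- assert_count(target_year, "target_year")
  if (target_year < 2020L || target_year > 2030L) {
    abort(sprintf("`target_year` must lie in [2020, 2030], got %d.",
                  target_year),
          class = "fps_input_error")
  }
  target_year
}

#' Personnel-cost inflation factor
#'
#' Personnel costs are inflated with country-specific GDP-deflator growth
#' rates: the observed/projected annual rates for 2021-2024, then the
#' arithmetic mean of those four rates for every year 2025 onwards:
#'
#' \deqn{F(T) = \prod_{y=2021}^{\min(T,2024)} (1+r_y) \cdot
#'   (1+\bar r)^{\max(0, T-2024)}}
#'
#' so `target_year = 2020` gives 1.
#'
#' @param rates_2021_2024 Numeric length 4: annual rates for 2021, 2022,
#'   2023, 2024 (decimals).
#' @param target_year Year in \[2020, 2030\].
#' @return The cumulative multiplier.
#' @examples
#' personnel_factor(rep(0.10, 4), 2030)  # 1.1^10
#' @export
personnel_factor <- function(rates_2021_2024, target_year) {
  if (!is.numeric(rates_2021_2024) || length(rates_2021_2024) != 4L ||
      any(!is.finite(rates_2021_2024))) {
    abort("`rates_2021_2024` must be four finite annual rates.",
          class = "fps_input_error")
  }
  target_year <- check_cost_year(target_year)
  n_observed <- min(target_year, 2024L) - 2020L
  observed <- if (n_observed > 0L) {
    prod(1 + rates_2021_2024[seq_len(n_observed)])
  } else 1
  extrapolated <- (1 + mean(rates_2021_2024))^max(0L, target_year - 2024L)
  observed * extrapolated
}

#' Drugs-and-supplies inflation factor
#'
#' Drugs and supply costs are inflated with a single constant US annual
#' inflation rate (representing the 2015-2019 average) compounded from the
#' 2020 base: `(1 + us_rate)^(target_year - 2020)`.
#'
#' @param us_rate Annual US inflation rate (decimal, nonnegative).
#' @param target_year Year in \[2020, 2030\].
#' @return The cumulative multiplier.
#' @export
drugs_supplies_factor <- function(us_rate, target_year) {
  assert_number(us_rate, "us_rate", lower = 0)
  target_year <- check_cost_year(target_year)
  (1 + us_rate)^(target_year - 2020L)
}

#' Commodity-cost inflation factor
#'
#' Contraceptive commodity costs are held flat over 2020-2030 (a
#' conservative choice: observed commodity prices from major suppliers
#' fell over 2015-2019), so the factor is always 1.
#'
#' @param target_year Year in \[2020, 2030\].
#' @return 1.0.
#' @export
commodity_factor <- function(target_year) {
  check_cost_year(target_year)
  1.0
}

#' Total annual direct cost per user of a method
#'
#' The total average cost per modern method per user-year is the sum of
#' the three inflated components:
#' `personnel x personnel_factor + drugs_supplies x drugs_supplies_factor
#' + commodity x commodity_factor`, in nominal target-year USD.
#'
#' @param personnel,drugs_supplies,commodity Base-year (2020) USD per
#'   user-year; vectorized over methods.
#' @param rates_2021_2024 The country's four annual GDP-deflator rates.
#' @param us_rate US annual inflation rate for drugs and supplies.
#' @param target_year Year in \[2020, 2030\].
#' @return USD per user-year, same length as the component inputs.
#' @export
cost_per_user <- function(personnel, drugs_supplies, commodity,
                          rates_2021_2024, us_rate, target_year) {
  if (any(c(personnel, drugs_supplies, commodity) < 0)) {
    abort("Cost components must be nonnegative.", class = "fps_input_error")
  }
  personnel * personnel_factor(rates_2021_2024, target_year) +
    drugs_supplies * drugs_supplies_factor(us_rate, target_year) +
    commodity * commodity_factor(target_year)
}

#' Total annual direct cost for a scenario's users
#'
#' Allocates the modern users across methods with the (time-invariant)
#' method mix and prices each group at its per-user cost:
#' `sum_k users x mix_k x cost_k`. With users in thousands and costs in
#' USD per user-year, the result is in USD thousands per year.
#'
#' @param users_modern Modern-method users, thousands (scalar).
#' @param mix Method mix: tibble `method,share` or named numeric vector.
#' @param costs_per_user Per-user annual costs by method: named numeric
#'   vector (USD/user-year) covering every method in the mix.
#' @return Annual total direct cost, USD thousands.
#' @export
total_cost <- function(users_modern, mix, costs_per_user) {
  mix <- as_named_vector(mix, "share")
  if (is.null(names(costs_per_user))) {
    abort("`costs_per_user` must be a named vector keyed by method.",
          class = "fps_input_error")
  }
  missing_methods <- setdiff(names(mix), names(costs_per_user))
  if (length(missing_methods) > 0L) {
    abort(sprintf("No per-user cost for method(s): %s.",
                  paste(missing_methods, collapse = ", ")),
          class = "fps_input_error")
  }
  sum(users_modern * mix * costs_per_user[names(mix)])
}
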