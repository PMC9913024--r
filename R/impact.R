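#' Annual unintended pregnancies under a scenario
#'
#' Pregnancies among women who want to avoid one arise from two groups:
#' modern-method users, who conceive at their method's age-adjusted annual
#' failure rate, and women with an unmet need for modern methods
#' (traditional users or non-users), who conceive at the non-user
#' pregnancy rate:
#'
#' \deqn{UP = \sum_k users \cdot mix_k \cdot failure_k + unmet \cdot rate}
#'
#' The method mix is held constant over time and the rates are annual
#' per-woman-year probabilities applied to the scenario-year counts; women
#' with no desire to avoid pregnancy do not contribute by construction.
#'
#' @param users_modern Modern-method users, thousands. Vectorized (one
#'   element per country).
#' @param unmet_modern Women with unmet need for modern methods,
#'   thousands. Same length as `users_modern`.
#' @param mix Method mix: tibble `method,share` or a named numeric vector
#'   of shares summing to 1.
#' @param failure_rates Tibble `method,annual_failure_rate` or named
#'   numeric vector; must cover every method in `mix`.
#' @param pregnancy_rate Annual pregnancy probability for women with
#'   unmet need for modern methods: a scalar (default 0.448, the median
#'   of the country-specific distribution for this group) or a tibble
#'   `country,pregnancy_rate` resolved via `country`.
#' @param country Country identifier(s); required when `pregnancy_rate`
#'   is a per-country table.
#' @return Annual unintended pregnancies, thousands per year.
#' @examples
#' unintended_pregnancies(1000, 100,
#'   mix = c(method_1 = 1), failure_rates = c(method_1 = 0.05))  # 94.8
#' @export
unintended_pregnancies <- function(users_modern, unmet_modern, mix,
                                   failure_rates, pregnancy_rate = 0.448,
                                   country = NULL) {
  mix <- as_named_vector(mix, "share")
  failure_rates <- as_named_vector(failure_rates, "annual_failure_rate")
  missing_methods <- setdiff(names(mix), names(failure_rates))
  if (length(missing_methods) > 0L) {
    abort(sprintf("No failure rate for method(s): %s.",
                  paste(missing_methods, collapse = ", ")),
          class = "fps_input_error")
  }
  if (length(users_modern) != length(unmet_modern)) {
    abort("`users_modern` and `unmet_modern` must have the same length.",
          class = "fps_input_error")
  }
  rate <- resolve_pregnancy_rate(pregnancy_rate, country,
                                 n = length(users_modern))
  method_rate <- sum(mix * failure_rates[names(mix)])
  users_modern * method_rate + unmet_modern * rate
}

# Accept tibble (method + value column) or named numeric vector.
as_named_vector <- function(x, value_col) {
  if (is.data.frame(x)) {
    require_columns(x, c("method", value_col), "Method table")
    stats::setNames(as.numeric(x[[value_col]]), x$method)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    abort(sprintf("Expected a `method,%s` table or a named numeric vector.",
                  value_col),
          class = "fps_input_error")
  }
}

resolve_pregnancy_rate <- function(pregnancy_rate, country, n) {
  if (is.data.frame(pregnancy_rate)) {
    require_columns(pregnancy_rate, c("country", "pregnancy_rate"),
                    "Pregnancy-rate table")
    if (is.null(country)) {
      abort("`country` is required with a per-country pregnancy-rate table.",
            class = "fps_input_error")
    }
    idx <- match(country, pregnancy_rate$country)
    if (anyNA(idx)) {
      abort(sprintf("No pregnancy rate for country %s.",
                    country[which(is.na(idx))[1L]]),
            class = "fps_input_error")
    }
    rate <- pregnancy_rate$pregnancy_rate[idx]
  } else {
    assert_number(pregnancy_rate, "pregnancy_rate")
    rate <- rep(pregnancy_rate, n)
  }
  if (any(rate <= 0 | rate >= 1)) {
    abort("Pregnancy rate(s) must lie strictly within (0, 1).",
          class = "fps_input_error")
  }
  rate
}
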