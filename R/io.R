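# CSV dialects for the pipeline inputs and outputs. All readers return
# tibbles, validate schema (naming missing columns) and value ranges
# (reporting offending row numbers).

read_csv_strict <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "fps_input_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

require_columns <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("%s is missing column(s): %s.",
                  what, paste(missing_cols, collapse = ", ")),
          class = "fps_parse_error")
  }
  invisible(df)
}

check_range <- function(df, col, what, lower = -Inf, upper = Inf,
                        strict_lower = FALSE) {
  v <- df[[col]]
  bad <- !is.finite(v) | v > upper |
    (if (strict_lower) v <= lower else v < lower)
  if (any(bad)) {
    abort(sprintf("%s: column `%s` out of range at row(s) %s.",
                  what, col, paste(head(which(bad), 5L), collapse = ", ")),
          class = "fps_parse_error")
  }
  invisible(df)
}

#' Read a table of women of reproductive age by country and year
#'
#' Dialect: `country,year,wra_thousands` with strictly positive counts in
#' thousands of women aged 15-49.
#'
#' @param path CSV path.
#' @return A tibble with columns `country`, `year`, `wra_thousands`.
#' @export
read_population <- function(path) {
  df <- read_csv_strict(path)
  require_columns(df, c("country", "year", "wra_thousands"), "Population table")
  check_range(df, "wra_thousands", "Population table", lower = 0,
              strict_lower = TRUE)
  tibble::as_tibble(df[c("country", "year", "wra_thousands")])
}

#' Read a modern-method mix
#'
#' Dialect: `method,share`. Shares are nonnegative and must sum to 1
#' within 1e-9; the mix is held constant over time.
#'
#' @param path CSV path.
#' @return A tibble with columns `method`, `share`.
#' @export
read_method_mix <- function(path) {
  df <- read_csv_strict(path)
  require_columns(df, c("method", "share"), "Method mix")
  check_range(df, "share", "Method mix", lower = 0)
  if (abs(sum(df$share) - 1) > 1e-9) {
    abort(sprintf("Method mix shares must sum to 1 (got %.12f).",
                  sum(df$share)),
          class = "fps_parse_error")
  }
  tibble::as_tibble(df[c("method", "share")])
}

#' Read per-method annual failure rates
#'
#' Dialect: `method,annual_failure_rate`; rates are annual per-user-year
#' pregnancy probabilities in \[0, 0.5).
#'
#' @param path CSV path.
#' @return A tibble with columns `method`, `annual_failure_rate`.
#' @export
read_failure_rates <- function(path) {
  df <- read_csv_strict(path)
  require_columns(df, c("method", "annual_failure_rate"), "Failure-rate table")
  check_range(df, "annual_failure_rate", "Failure-rate table",
              lower = 0, upper = 0.5 - 1e-12)
  tibble::as_tibble(df[c("method", "annual_failure_rate")])
}

#' Read per-method cost components
#'
#' Dialect: `country,method,personnel,drugs_supplies,commodity` (base-year
#' USD per user-year). The `country` column is optional: without it the
#' components are broadcast to every country.
#'
#' @param path CSV path.
#' @return A tibble with columns `method`, `personnel`, `drugs_supplies`,
#'   `commodity` and, when present in the file, `country`.
#' @export
read_cost_components <- function(path) {
  df <- read_csv_strict(path)
  require_columns(df, c("method", "personnel", "drugs_supplies", "commodity"),
                  "Cost-components table")
  for (col in c("personnel", "drugs_supplies", "commodity")) {
    check_range(df, col, "Cost-components table", lower = 0)
  }
  keep <- intersect(c("country", "method", "personnel", "drugs_supplies",
                      "commodity"), names(df))
  tibble::as_tibble(df[keep])
}

#' Read country inflation rates for 2021-2024
#'
#' Dialect: `country,rate_2021,rate_2022,rate_2023,rate_2024`; annual
#' GDP-deflator growth rates as decimals. The single US rate used for
#' drugs-and-supplies inflation lives in the run config, not in this file.
#'
#' @param path CSV path.
#' @return A tibble with the five columns above.
#' @export
read_inflation <- function(path) {
  df <- read_csv_strict(path)
  cols <- c("country", paste0("rate_", 2021:2024))
  require_columns(df, cols, "Inflation table")
  for (col in cols[-1L]) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0L) {
      abort(sprintf("Inflation table: non-finite `%s` at row(s) %s.",
                    col, paste(head(bad, 5L), collapse = ", ")),
            class = "fps_parse_error")
    }
  }
  tibble::as_tibble(df[cols])
}

#' Read country-specific pregnancy rates for non-users
#'
#' Dialect: `country,pregnancy_rate`; annual pregnancy probability in
#' (0, 1) for women with unmet need for modern methods (traditional users
#' or non-users who want to avoid pregnancy). Optional input: a scalar
#' rate (default 0.448) may be used instead.
#'
#' @param path CSV path.
#' @return A tibble with columns `country`, `pregnancy_rate`.
#' @export
read_pregnancy_rates <- function(path) {
  df <- read_csv_strict(path)
  require_columns(df, c("country", "pregnancy_rate"), "Pregnancy-rate table")
  check_range(df, "pregnancy_rate", "Pregnancy-rate table",
              lower = 0, upper = 1, strict_lower = TRUE)
  tibble::as_tibble(df[c("country", "pregnancy_rate")])
}
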