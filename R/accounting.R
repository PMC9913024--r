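#' Convert scenario proportions to absolute numbers of women
#'
#' Multiplies the scenario proportions by the count of women of
#' reproductive age in the target year: users of modern methods are
#' `modern x WRA` and women with an unmet need for modern methods are
#' `trad_plus_unmet x WRA`, both in thousands. The ratio
#' `users / (users + unmet)` reproduces the scenario demand-satisfied
#' proportion exactly.
#'
#' @param props A tibble of scenario proportions as returned by
#'   [scenario_proportions_all()] (or a single-country row from
#'   [scenario_proportions()]); must carry `country`, `target_year`,
#'   `modern`, `trad_plus_unmet`.
#' @param pop Population table (`country,year,wra_thousands`), e.g. from
#'   [read_population()] or [generate_population()].
#' @return `props` with columns `wra_thousands`, `users_modern_thousands`
#'   and `unmet_modern_thousands` appended.
#' @export
absolute_numbers <- function(props, pop) {
  stopifnot(is.data.frame(props), is.data.frame(pop))
  if (any(pop$wra_thousands <= 0)) {
    abort("Population counts must be strictly positive.",
          class = "fps_input_error")
  }
  key <- paste(pop$country, pop$year)
  idx <- match(paste(props$country, props$target_year), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    abort(sprintf("No population count for country %s in year %d.",
                  props$country[bad], props$target_year[bad]),
          class = "fps_input_error")
  }
  wra <- pop$wra_thousands[idx]
  dplyr::mutate(props,
                wra_thousands = wra,
                users_modern_thousands = .data$modern * wra,
                unmet_modern_thousands = .data$trad_plus_unmet * wra)
}

#' Aggregate country results within each scenario
#'
#' Sums users, unmet need, unintended pregnancies and costs over
#' countries. The aggregate percent of demand satisfied is the ratio of
#' sums, `100 x sum(users) / (sum(users) + sum(unmet))` — not the mean of
#' country percentages — so the aggregate row satisfies the same
#' accounting identity as every country row.
#'
#' @param results Country-level results: one row per (country, scenario)
#'   with columns `country`, `scenario`, `users_modern_thousands`,
#'   `unmet_modern_thousands` and optionally
#'   `unintended_pregnancies_thousands`, `total_cost_usd_thousands`.
#' @return A tibble with one row per scenario: `scenario`, `n_countries`,
#'   `percent_demand_satisfied`, `users_modern_thousands`,
#'   `unmet_modern_thousands`, and sums of any impact/cost columns
#'   present. The per-scenario country sets are kept in the `"countries"`
#'   attribute for the benefit of [compare_scenarios()].
#' @export
aggregate_results <- function(results) {
  stopifnot(is.data.frame(results))
  req <- c("country", "scenario", "users_modern_thousands",
           "unmet_modern_thousands")
  missing_cols <- setdiff(req, names(results))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Country results missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "fps_input_error")
  }
  dup <- dplyr::count(results, .data$scenario, .data$country) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("Duplicate country %s in scenario \"%s\".",
                  dup$country[1L], dup$scenario[1L]),
          class = "fps_input_error")
  }
  opt <- intersect(c("unintended_pregnancies_thousands",
                     "total_cost_usd_thousands"), names(results))
  agg <- results |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      n_countries = dplyr::n(),
      users_modern_thousands = sum(.data$users_modern_thousands),
      unmet_modern_thousands = sum(.data$unmet_modern_thousands),
      dplyr::across(dplyr::all_of(opt), sum),
      .groups = "drop") |>
    dplyr::mutate(
      percent_demand_satisfied = 100 * .data$users_modern_thousands /
        (.data$users_modern_thousands + .data$unmet_modern_thousands),
      .after = "n_countries")
  attr(agg, "countries") <- lapply(
    split(results$country, results$scenario)[agg$scenario], sort)
  agg
}

comparison_quantities <- c(
  "percent_demand_satisfied",
  "users_modern_thousands",
  "unmet_modern_thousands",
  "unintended_pregnancies_thousands",
  "total_cost_usd_thousands")

#' Compare two aggregate scenario rows
#'
#' Builds the two-scenario comparison table (one row per reported
#' quantity, one column per scenario, plus an absolute difference column,
#' second scenario minus first) from pre-aggregated values. Differences
#' are taken on the unrounded values; any report rounding (3 significant
#' figures by default in [render_comparison()]) is applied afterwards.
#'
#' @param current,accelerated Aggregate rows — one-row data frames or
#'   named lists/vectors carrying (a subset of)
#'   `percent_demand_satisfied`, `users_modern_thousands`,
#'   `unmet_modern_thousands`, `unintended_pregnancies_thousands`,
#'   `total_cost_usd_thousands`.
#' @param names Length-2 character: labels for the two scenario columns.
#' @return A `scenario_comparison` tibble with columns `quantity`, the two
#'   scenario labels, and `difference`.
#' @export
compare_aggregates <- function(current, accelerated,
                               names = c("current", "accelerated")) {
  pick <- function(x) {
    x <- as.list(x)
    q <- intersect(comparison_quantities, base::names(x))
    vapply(x[q], as.numeric, numeric(1L))
  }
  a <- pick(current); b <- pick(accelerated)
  common <- intersect(base::names(a), base::names(b))
  if (length(common) == 0L) {
    abort("No comparable quantities between the two aggregate rows.",
          class = "fps_input_error")
  }
  common <- comparison_quantities[comparison_quantities %in% common]
  out <- tibble::tibble(
    quantity = common,
    !!names[1L] := unname(a[common]),
    !!names[2L] := unname(b[common]),
    difference = unname(b[common] - a[common]))
  class(out) <- c("scenario_comparison", class(out))
  out
}

#' Compare scenarios from country-level results
#'
#' Aggregates the country rows of two scenarios (checking both cover the
#' same country set) and lays them out as the comparison table: percent of
#' demand satisfied with modern methods, numbers of modern-method users
#' and of women with unmet need for modern methods (thousands), annual
#' unintended pregnancies (thousands), and annual total direct costs (USD
#' thousands), with an accelerated-minus-current difference column.
#'
#' @param results Country-level results covering both scenarios.
#' @param scenarios Length-2 character: the scenario labels to compare,
#'   in (baseline, comparator) order.
#' @return A `scenario_comparison` tibble; see [compare_aggregates()].
#' @export
compare_scenarios <- function(results,
                              scenarios = c("current", "accelerated")) {
  stopifnot(length(scenarios) == 2L)
  agg <- aggregate_results(
    dplyr::filter(results, .data$scenario %in% scenarios))
  sets <- attr(agg, "countries")
  if (!all(scenarios %in% agg$scenario)) {
    abort(sprintf("Scenario(s) not found in results: %s.",
                  paste(setdiff(scenarios, agg$scenario), collapse = ", ")),
          class = "fps_input_error")
  }
  sdiff <- c(setdiff(sets[[scenarios[1L]]], sets[[scenarios[2L]]]),
             setdiff(sets[[scenarios[2L]]], sets[[scenarios[1L]]]))
  if (length(sdiff) > 0L) {
    abort(sprintf("Scenario country sets differ; symmetric difference: %s.",
                  paste(sort(sdiff), collapse = ", ")),
          class = "fps_input_error")
  }
  rows <- split(agg, agg$scenario)
  compare_aggregates(rows[[scenarios[1L]]], rows[[scenarios[2L]]],
                     names = scenarios)
}

#' Render a comparison table as aligned text
#'
#' Values are rounded to `sigfigs` significant figures for display only;
#' the underlying comparison keeps full precision and its difference
#' column was computed before rounding.
#'
#' @param comparison A `scenario_comparison`.
#' @param sigfigs Significant figures for display (default 3).
#' @return A character vector of lines, invisibly printed with `cat()` by
#'   the `print` method.
#' @export
render_comparison <- function(comparison, sigfigs = 3L) {
  stopifnot(inherits(comparison, "scenario_comparison"))
  labels <- c(
    percent_demand_satisfied = "% of demand satisfied by modern methods",
    users_modern_thousands = "Women using modern methods (000s)",
    unmet_modern_thousands = "Women with unmet need for modern methods (000s)",
    unintended_pregnancies_thousands = "Unintended pregnancies (000s)",
    total_cost_usd_thousands = "Annual total direct costs ($ 000s)")
  fmt <- function(x) {
    vapply(x, function(v) format(signif(v, sigfigs), big.mark = ",",
                                 scientific = FALSE, trim = TRUE),
           character(1L))
  }
  body <- comparison
  body$quantity <- unname(labels[body$quantity])
  num_cols <- names(body)[-1L]
  cells <- cbind(body$quantity,
                 vapply(num_cols, function(cl) fmt(body[[cl]]),
                        character(nrow(body))))
  header <- c("Quantity", num_cols)
  widths <- pmax(nchar(header), apply(nchar(cells), 2L, max))
  pad <- function(v, w, right = FALSE) {
    formatC(v, width = w, flag = if (right) "" else "-")
  }
  line <- function(v) {
    paste(mapply(function(x, w, r) pad(x, w, r), v, widths,
                 c(FALSE, rep(TRUE, length(widths) - 1L))),
          collapse = "  ")
  }
  lines <- c(line(header),
             paste(rep("-", sum(widths) + 2L * (length(widths) - 1L)),
                   collapse = ""),
             apply(cells, 1L, line))
  lines
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(render_comparison(x), sep = "\n")
  invisible(x)
}
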