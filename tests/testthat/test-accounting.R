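props_row <- function(country = "C001", modern = 0.5, tpu = 0.2,
                      year = 2030L, scenario = "current") {
  tibble::tibble(country = country, scenario = scenario,
                 percentile = 50, target_year = year,
                 demand_satisfied = modern / (modern + tpu),
                 modern = modern, trad_plus_unmet = tpu,
                 total_demand = modern + tpu, clipped = FALSE)
}

result_row <- function(country, scenario, users, unmet, up = 0, cost = 0) {
  tibble::tibble(country = country, scenario = scenario,
                 demand_satisfied = users / (users + unmet),
                 users_modern_thousands = users,
                 unmet_modern_thousands = unmet,
                 unintended_pregnancies_thousands = up,
                 total_cost_usd_thousands = cost)
}

test_that("absolute numbers scale proportions by the WRA population", {
  pop <- tibble::tibble(country = "C001", year = 2030L,
                        wra_thousands = 1000)
  got <- absolute_numbers(props_row(), pop)
  expect_equal(got$users_modern_thousands, 500)
  expect_equal(got$unmet_modern_thousands, 200)
  # ratio identity survives the scaling exactly
  expect_equal(got$users_modern_thousands /
                 (got$users_modern_thousands + got$unmet_modern_thousands),
               got$demand_satisfied, tolerance = 1e-12)
  # zero or missing population is rejected by name
  expect_error(absolute_numbers(
    props_row(), tibble::tibble(country = "C001", year = 2030L,
                                wra_thousands = 0)),
    "strictly positive")
  expect_error(absolute_numbers(
    props_row(country = "C002"), pop), "C002")
})

test_that("aggregation reproduces the published percentages from counts", {
  cur <- aggregate_results(result_row("ALL", "current", 783000, 218000))
  acc <- aggregate_results(result_row("ALL", "accelerated", 876000, 177000))
  expect_equal(round(cur$percent_demand_satisfied), 78)
  expect_equal(round(acc$percent_demand_satisfied), 83)
})

test_that("aggregation is a plain sum with a ratio-of-sums percentage", {
  rows <- dplyr::bind_rows(
    result_row("A", "current", 100, 50, 10, 500),
    result_row("B", "current", 300, 60, 20, 900),
    result_row("C", "current", 50, 40, 5, 100))
  agg <- aggregate_results(rows)
  expect_equal(agg$users_modern_thousands, 450)
  expect_equal(agg$unmet_modern_thousands, 150)
  expect_equal(agg$unintended_pregnancies_thousands, 35)
  expect_equal(agg$total_cost_usd_thousands, 1500)
  expect_equal(agg$percent_demand_satisfied, 100 * 450 / 600)

  # single-country aggregate equals that country's values
  one <- aggregate_results(rows[2, ])
  expect_equal(one$users_modern_thousands, 300)
  expect_equal(one$percent_demand_satisfied,
               100 * rows$demand_satisfied[2])

  # permutation invariance and additivity over a disjoint partition
  perm <- aggregate_results(rows[c(3, 1, 2), ])
  expect_equal(perm$users_modern_thousands, agg$users_modern_thousands)
  part1 <- aggregate_results(rows[1:2, ])
  part2 <- aggregate_results(rows[3, ])
  expect_equal(part1$users_modern_thousands + part2$users_modern_thousands,
               agg$users_modern_thousands)

  # aggregate DS lies between the country extremes
  ds <- 100 * rows$demand_satisfied
  expect_gte(agg$percent_demand_satisfied, min(ds))
  expect_lte(agg$percent_demand_satisfied, max(ds))

  # a duplicated country is an input error
  expect_error(aggregate_results(dplyr::bind_rows(rows, rows[1, ])),
               "Duplicate")
})

test_that("comparison differences are taken on unrounded values", {
  cur <- list(percent_demand_satisfied = 78,
              users_modern_thousands = 783000,
              unmet_modern_thousands = 218000,
              unintended_pregnancies_thousands = 97000,
              total_cost_usd_thousands = 3990000)
  acc <- list(percent_demand_satisfied = 83,
              users_modern_thousands = 876000,
              unmet_modern_thousands = 177000,
              unintended_pregnancies_thousands = 83100,
              total_cost_usd_thousands = 4470000)
  cmp <- compare_aggregates(cur, acc)
  diffs <- stats::setNames(cmp$difference, cmp$quantity)
  expect_equal(unname(diffs["users_modern_thousands"]), 93000)
  expect_equal(unname(diffs["unmet_modern_thousands"]), -41000)
  expect_equal(unname(diffs["unintended_pregnancies_thousands"]), -13900)
  expect_equal(unname(diffs["total_cost_usd_thousands"]), 480000)
  expect_equal(unname(diffs["percent_demand_satisfied"]), 5)

  # identical rows give an all-zero difference column
  same <- compare_aggregates(cur, cur)
  expect_true(all(same$difference == 0))
})

test_that("comparing scenarios requires matching country sets", {
  rows <- dplyr::bind_rows(
    result_row("A", "current", 100, 50),
    result_row("B", "current", 300, 60),
    result_row("A", "accelerated", 120, 30))
  expect_error(compare_scenarios(rows), "symmetric difference.*B")
})

test_that("rendered comparison rounds to significant figures for display", {
  cmp <- compare_aggregates(
    list(users_modern_thousands = 783456, unmet_modern_thousands = 218321),
    list(users_modern_thousands = 876123, unmet_modern_thousands = 177456))
  lines <- render_comparison(cmp, sigfigs = 3)
  expect_true(any(grepl("783,000", lines)))
  expect_true(any(grepl("876,000", lines)))
  # underlying values keep full precision
  expect_equal(cmp$accelerated[cmp$quantity == "users_modern_thousands"],
               876123)
})
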