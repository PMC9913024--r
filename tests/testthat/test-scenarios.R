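test_that("demand satisfied is modern use over total demand", {
  expect_equal(demand_satisfied(0.30, 0.10, 0.10), 0.6)
  expect_warning(ds0 <- demand_satisfied(0, 0, 0), "Zero total demand")
  expect_equal(ds0, 0)
  # the identity also holds in absolute-number form: the published
  # aggregate counts round back to the published percentage
  expect_equal(round(100 * 783000 / (783000 + 218000)), 78)
  # vectorized, with mixed zero and nonzero demand
  expect_warning(
    v <- demand_satisfied(c(0.3, 0), c(0.1, 0), c(0.1, 0)))
  expect_equal(v, c(0.6, 0))
})

test_that("percentile estimator follows the declared interpolation rule", {
  expect_equal(fp_quantile(c(1, 2, 3), 50), 2)
  expect_equal(fp_quantile(0:10, 90), 9)
  expect_error(fp_quantile(numeric(0), 50), "empty")
  expect_error(fp_quantile(c(1, NA), 50), "non-finite")
})

test_that("percentile estimator matches the brute-force oracle", {
  set.seed(991)
  for (n in 2:12) {
    for (rep in 1:40) {
      x <- runif(n) * 100
      for (p in c(1, 5, 10, 25, 50, 75, 90, 95, 99, runif(1, 0, 100))) {
        expect_equal(fp_quantile(x, p), oracle_quantile(x, p),
                     tolerance = 1e-12)
      }
    }
  }
  # odd-length median is the middle order statistic exactly
  x <- sample(c(4, 9, 1, 7, 2))
  expect_identical(fp_quantile(x, 50), 4)
})

test_that("change distribution is computed within each trajectory", {
  years <- c(2019, 2030)
  spec <- scenario_spec("current", 50)
  # all samples identical: DS 0.5 -> 0.6 gives a constant 0.1 change
  traj <- constant_traj(rbind(c(0.25, 0.15, 0.10), c(0.30, 0.10, 0.10)),
                        years, n_samples = 4)
  expect_equal(change_distribution(traj, "C001", spec), rep(0.1, 4))
  # no movement between the years -> all-zero change
  flat <- constant_traj(rbind(c(0.25, 0.15, 0.10), c(0.25, 0.15, 0.10)),
                        years, n_samples = 4)
  expect_equal(change_distribution(flat, "C001", spec), rep(0, 4))
  expect_error(change_distribution(traj, "C999", spec), "C999")
  expect_error(
    change_distribution(traj, "C001", scenario_spec("x", 50, 2019, 2029)),
    "2029")
})

test_that("change distribution matches an independent per-sample loop", {
  traj <- generate_trajectories(small_config(n_samples = 30L))
  spec <- scenario_spec("current", 50)
  for (cc in traj$countries) {
    got <- change_distribution(traj, cc, spec)
    manual <- vapply(seq_len(traj$n_samples), function(s) {
      ds <- function(y) {
        m <- traj$modern[cc, s, as.character(y)]
        t <- traj$traditional[cc, s, as.character(y)]
        u <- traj$unmet[cc, s, as.character(y)]
        m / (m + t + u)
      }
      ds(2030) - ds(2019)
    }, numeric(1))
    expect_equal(got, manual, tolerance = 1e-12)
    expect_equal(mean(got), mean(manual), tolerance = 1e-12)
  }
})

test_that("scenario proportions match a hand computation on 3 samples", {
  years <- c(2019, 2030)
  # 3 samples, chosen so baseline and change distributions are easy to
  # order by hand
  s2019 <- rbind(c(0.30, 0.10, 0.10),   # DS = 0.6
                 c(0.20, 0.10, 0.10),   # DS = 0.5
                 c(0.40, 0.05, 0.05))   # DS = 0.8
  s2030 <- rbind(c(0.35, 0.08, 0.07),   # DS = 0.7,  change 0.1
                 c(0.33, 0.11, 0.11),   # DS = 0.6,  change 0.1...
                 c(0.45, 0.03, 0.02))   # DS = 0.9,  change 0.1
  traj <- build_traj(list(C001 = list(s2019, s2030)), years)

  # hand computation, independent of package internals:
  ds_base <- c(0.6, 0.5, 0.8)            # median 0.6
  ds_2030 <- c(0.7, 0.6, 0.9)
  change <- ds_2030 - ds_base            # 0.1, 0.1, 0.1
  totals_2030 <- c(0.5, 0.55, 0.5)       # median 0.5
  # p = 90 on 3 sorted values {0.1, 0.1, 0.1} -> 0.1
  expected_ds <- 0.6 + 0.1               # 0.7
  got <- scenario_proportions(traj, "C001", scenario_spec("acc", 90))
  expect_equal(got$demand_satisfied, expected_ds, tolerance = 1e-12)
  expect_equal(got$total_demand, 0.5, tolerance = 1e-12)
  expect_equal(got$modern, 0.7 * 0.5, tolerance = 1e-12)
  expect_equal(got$trad_plus_unmet, 0.5 - 0.35, tolerance = 1e-12)
  expect_false(got$clipped)

  # a distinct change ordering exercises the interpolation: shift sample 3
  s2030b <- s2030
  s2030b[3, ] <- c(0.35, 0.075, 0.075)   # DS = 0.7, change -0.1
  trajb <- build_traj(list(C001 = list(s2019, s2030b)), years)
  # changes {0.1, 0.1, -0.1} sorted: (-0.1, 0.1, 0.1);
  # p = 90: h = 2 * 0.9 = 1.8 -> 0.1
  gotb <- scenario_proportions(trajb, "C001", scenario_spec("acc", 90))
  expect_equal(gotb$demand_satisfied, 0.6 + 0.1, tolerance = 1e-12)
  # p = 25: h = 0.5 -> midpoint of (-0.1, 0.1) = 0
  gotc <- scenario_proportions(trajb, "C001", scenario_spec("low", 25))
  expect_equal(gotc$demand_satisfied, 0.6, tolerance = 1e-12)
})

test_that("scenario demand satisfied is monotone in the percentile", {
  traj <- generate_trajectories(small_config(n_samples = 80L))
  specs <- lapply(c(10, 30, 50, 70, 90), function(p) {
    scenario_spec(paste0("p", p), p)
  })
  for (cc in traj$countries) {
    ds <- vapply(specs, function(sp) {
      scenario_proportions(traj, cc, sp)$demand_satisfied
    }, numeric(1))
    expect_true(all(diff(ds) >= -1e-12))
  }
})

test_that("identical trajectories make the output percentile-independent", {
  traj <- constant_traj(rbind(c(0.25, 0.15, 0.10), c(0.30, 0.10, 0.10)),
                        c(2019, 2030), n_samples = 5)
  p50 <- scenario_proportions(traj, "C001", scenario_spec("a", 50))
  p90 <- scenario_proportions(traj, "C001", scenario_spec("b", 90))
  expect_equal(p50$demand_satisfied, p90$demand_satisfied, tolerance = 1e-12)
  expect_equal(p50$modern, p90$modern, tolerance = 1e-12)
  # and the value is the deterministic trajectory's own DS
  expect_equal(p50$demand_satisfied, 0.30 / 0.50, tolerance = 1e-12)
})

test_that("the accounting identity and clipping behave as declared", {
  traj <- generate_trajectories(small_config(n_samples = 40L))
  props <- scenario_proportions_all(traj, scenario_spec("acc", 90))
  expect_equal(props$modern + props$trad_plus_unmet, props$total_demand,
               tolerance = 1e-12)
  expect_true(all(props$demand_satisfied >= 0 & props$demand_satisfied <= 1))

  # force a clip: a high median baseline DS (0.745) plus a 90th-percentile
  # change of 0.405 overshoots 1
  s2019 <- rbind(c(0.500, 0.003, 0.002),   # DS = 0.990
                 c(0.250, 0.150, 0.100))   # DS = 0.5
  s2030 <- rbind(c(0.500, 0.003, 0.002),   # DS = 0.990, change 0
                 c(0.475, 0.015, 0.010))   # DS = 0.95,  change 0.45
  traj2 <- build_traj(list(C001 = list(s2019, s2030)), c(2019, 2030))
  got <- scenario_proportions(traj2, "C001", scenario_spec("acc", 90))
  expect_true(got$clipped)
  expect_equal(got$demand_satisfied, 1)
})
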