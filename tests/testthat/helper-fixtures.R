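# Shared fixtures and independent oracles, all built in code.

# Brute-force percentile oracle: sort, then interpolate linearly between
# order statistics with p = 0 -> minimum, p = 100 -> maximum. Written
# independently of the implementation under test.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100
  lo <- floor(h)
  if (lo >= n - 1) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# A hand-built trajectory set: `values` is a list with one element per
# country, each a list of per-year S x 3 matrices (modern, traditional,
# unmet), allowing exact control of every sample.
build_traj <- function(values, years) {
  countries <- names(values)
  ns <- nrow(values[[1]][[1]])
  ny <- length(years)
  dn <- list(countries, NULL, as.character(years))
  modern <- array(NA_real_, c(length(countries), ns, ny), dimnames = dn)
  traditional <- modern
  unmet <- modern
  for (i in seq_along(countries)) {
    for (j in seq_len(ny)) {
      m <- values[[i]][[j]]
      modern[i, , j] <- m[, 1]
      traditional[i, , j] <- m[, 2]
      unmet[i, , j] <- m[, 3]
    }
  }
  trajectory_set(modern, traditional, unmet)
}

# Constant-in-sample trajectory: every sample identical, per-year triples
# given as a 3-column matrix with one row per year.
constant_traj <- function(per_year, years, n_samples = 3, country = "C001") {
  vals <- lapply(seq_along(years), function(j) {
    matrix(rep(per_year[j, ], each = n_samples), nrow = n_samples)
  })
  build_traj(stats::setNames(list(vals), country), years)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_countries = 4L, n_samples = 50L, seed = 11L, n_methods = 3L),
    list(...))
  do.call(simulation_config, args)
}
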