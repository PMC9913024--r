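#' Posterior trajectory samples of family-planning proportions
#'
#' A `trajectory_set` holds, for every country, posterior sample and year,
#' the triple of proportions among women of reproductive age (WRA):
#' modern contraceptive use, traditional contraceptive use, and unmet need
#' for family planning. The three components are jointly constrained to the
#' simplex (each in \[0, 1\], componentwise sum at most 1), mirroring the
#' joint probabilistic projections of contraceptive prevalence and unmet
#' need that the scenario machinery consumes.
#'
#' Internally the values are stored as three numeric arrays of dimension
#' `country x sample x year`, which keeps percentile computations fast; use
#' [as_trajectory_tibble()] / [read_trajectories()] for the long-format
#' tabular view.
#'
#' @param modern,traditional,unmet Numeric arrays of identical dimension
#'   `n_countries x n_samples x n_years`. `modern` must carry dimnames:
#'   country identifiers on the first margin and years (as characters) on
#'   the third.
#' @return An object of class `trajectory_set` with fields `countries`,
#'   `years`, `n_samples`, `modern`, `traditional`, `unmet`.
#' @seealso [generate_trajectories()], [scenario_proportions()]
#' @export
trajectory_set <- function(modern, traditional, unmet) {
  if (!is.array(modern) || length(dim(modern)) != 3L) {
    abort("`modern` must be a 3-d array (country x sample x year).",
          class = "fps_input_error")
  }
  if (!identical(dim(modern), dim(traditional)) ||
      !identical(dim(modern), dim(unmet))) {
    abort("`modern`, `traditional` and `unmet` must have identical dimensions.",
          class = "fps_input_error")
  }
  dn <- dimnames(modern)
  if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[3L]])) {
    abort("`modern` must have country dimnames (margin 1) and year dimnames (margin 3).",
          class = "fps_input_error")
  }
  countries <- dn[[1L]]
  years <- as.integer(dn[[3L]])
  x <- structure(
    list(countries = countries, years = years,
         n_samples = dim(modern)[2L],
         modern = modern, traditional = traditional, unmet = unmet),
    class = "trajectory_set"
  )
  validate_trajectory_set(x)
}

#' Validate a trajectory set
#'
#' Checks the simplex constraint (each component in \[0, 1\], componentwise
#' sum at most 1 up to numerical tolerance), that at least two posterior
#' samples are present, and that the year grid is strictly increasing with
#' no gaps in coverage (the array representation guarantees completeness).
#'
#' @param x A `trajectory_set`.
#' @param tol Numerical tolerance on the simplex-sum constraint.
#' @return `x`, invisibly usable, after validation.
#' @export
validate_trajectory_set <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "trajectory_set"))
  if (x$n_samples < 2L) {
    abort("A trajectory_set needs at least 2 posterior samples.",
          class = "fps_input_error")
  }
  if (length(x$years) < 2L || any(diff(x$years) <= 0L)) {
    abort("Years must be strictly increasing and span at least 2 years.",
          class = "fps_input_error")
  }
  vals <- c(x$modern, x$traditional, x$unmet)
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort("Trajectory proportions contain missing or non-finite values.",
          class = "fps_input_error")
  }
  if (any(vals < -tol) || any(vals > 1 + tol)) {
    abort("Trajectory proportions must lie in [0, 1].",
          class = "fps_input_error")
  }
  total <- x$modern + x$traditional + x$unmet
  if (any(total > 1 + tol)) {
    bad <- which(total > 1 + tol, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "Simplex violation: modern + traditional + unmet > 1 for country %s, sample %d, year %s.",
      x$countries[bad[1L]], bad[2L], x$years[bad[3L]]),
      class = "fps_input_error")
  }
  x
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d countries x %d samples x %d years (%d-%d)\n",
    length(x$countries), x$n_samples, length(x$years),
    min(x$years), max(x$years)))
  invisible(x)
}

#' Long-format tabular view of a trajectory set
#'
#' @param traj A `trajectory_set`.
#' @return A tibble with columns `country`, `sample`, `year`, `modern`,
#'   `traditional`, `unmet`, sorted by country, sample, year.
#' @export
as_trajectory_tibble <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  nc <- length(traj$countries); ns <- traj$n_samples; ny <- length(traj$years)
  grid <- expand.grid(country = traj$countries, sample = seq_len(ns),
                      year = traj$years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  out <- tibble::tibble(
    country = grid$country,
    sample = as.integer(grid$sample),
    year = as.integer(grid$year),
    modern = as.vector(traj$modern),
    traditional = as.vector(traj$traditional),
    unmet = as.vector(traj$unmet)
  )
  dplyr::arrange(out, .data$country, .data$sample, .data$year)
}

#' Build a trajectory set from a long-format table
#'
#' The table must hold one row per (country, sample, year) with no gaps:
#' every country must carry every sample index for every year.
#'
#' @param df A data frame with columns `country`, `sample`, `year`,
#'   `modern`, `traditional`, `unmet`.
#' @return A `trajectory_set`.
#' @export
trajectory_set_from_tibble <- function(df) {
  req <- c("country", "sample", "year", "modern", "traditional", "unmet")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Trajectory table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "fps_parse_error")
  }
  for (col in c("sample", "year", "modern", "traditional", "unmet")) {
    v <- df[[col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad) > 0L) {
      abort(sprintf("Non-numeric or missing `%s` at row(s): %s.",
                    col, paste(head(bad, 5L), collapse = ", ")),
            class = "fps_parse_error")
    }
  }
  countries <- sort(unique(as.character(df$country)))
  samples <- sort(unique(as.integer(df$sample)))
  years <- sort(unique(as.integer(df$year)))
  nc <- length(countries); ns <- length(samples); ny <- length(years)
  if (nrow(df) != nc * ns * ny) {
    abort(sprintf(
      "Incomplete trajectory table: expected %d rows (%d countries x %d samples x %d years), got %d.",
      nc * ns * ny, nc, ns, ny, nrow(df)),
      class = "fps_parse_error")
  }
  ci <- match(as.character(df$country), countries)
  si <- match(as.integer(df$sample), samples)
  yi <- match(as.integer(df$year), years)
  idx <- ci + nc * (si - 1L) + nc * ns * (yi - 1L)
  if (anyDuplicated(idx) > 0L) {
    abort("Duplicate (country, sample, year) rows in trajectory table.",
          class = "fps_parse_error")
  }
  dim3 <- c(nc, ns, ny)
  dn <- list(countries, NULL, as.character(years))
  mk <- function(v) {
    a <- array(NA_real_, dim3, dimnames = dn)
    a[idx] <- as.numeric(v)
    a
  }
  trajectory_set(mk(df$modern), mk(df$traditional), mk(df$unmet))
}

#' Read posterior trajectories from CSV
#'
#' Expects the long-format dialect with header exactly
#' `country,sample,year,modern,traditional,unmet`; proportions are decimals
#' in \[0, 1\]. Malformed rows are reported with their row numbers and a
#' missing column is named in the error.
#'
#' @param path Path to a CSV file.
#' @return A `trajectory_set`.
#' @export
read_trajectories <- function(path) {
  df <- read_csv_strict(path)
  trajectory_set_from_tibble(df)
}

#' Write posterior trajectories to CSV
#'
#' Inverse of [read_trajectories()]: writing then reading yields an equal
#' `trajectory_set`.
#'
#' @param traj A `trajectory_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  readr::write_csv(as_trajectory_tibble(traj), path)
  invisible(path)
}
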