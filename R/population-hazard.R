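#' Age-specific population hazard series
#'
#' The pooled, age-specific hazard rate of cancer occurrence in the whole
#' population (susceptible and resistant individuals together), with one
#' value and standard error per age-grid interval. This is the observable
#' quantity from which the susceptible-pool size and the individual hazard
#' rate are derived.
#'
#' @param rate Numeric vector of hazard rates, one per grid interval.
#' @param se Numeric vector of standard errors, same length.
#' @param grid An [age_grid()].
#' @param stratum Label for the population stratum.
#' @param per_100k If `TRUE` (default), `rate` and `se` are given in cases
#'   per 100,000 person-years and are rescaled to events per person-year for
#'   internal storage.
#' @return An object of class `population_hazard` with fields `rate` and
#'   `se` in events per person-year, `grid` and `stratum`.
#' @export
population_hazard <- function(rate, se, grid = age_grid(),
                              stratum = "unlabelled", per_100k = TRUE) {
  stopifnot(is_age_grid(grid),
            length(rate) == grid$n_intervals, length(se) == length(rate),
            all(is.finite(rate)), all(is.finite(se)),
            all(rate >= 0), all(se >= 0))
  s <- if (per_100k) 1e5 else 1
  structure(list(rate = as.numeric(rate) / s, se = as.numeric(se) / s,
                 grid = grid, stratum = as.character(stratum)),
            class = "population_hazard")
}

#' @export
print.population_hazard <- function(x, ...) {
  cat(sprintf("<population_hazard> stratum '%s', %d intervals\n",
              x$stratum, x$grid$n_intervals))
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' @export
as.data.frame.population_hazard <- function(x, ...) {
  data.frame(age_midpoint = x$grid$midpoints,
             rate_per_100k = x$rate * 1e5,
             se_per_100k = x$se * 1e5,
             stratum = x$stratum)
}

#' Write a population hazard series to CSV (per 100,000 person-years)
#' @param x A [population_hazard()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_hazard <- function(x, path) {
  stopifnot(inherits(x, "population_hazard"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a population hazard series from CSV
#'
#' Accepts the output of [write_population_hazard()] or any CSV with columns
#' `age_midpoint`, `rate_per_100k`, `se_per_100k` (and optionally `stratum`).
#'
#' @param path CSV file path.
#' @param grid Optional [age_grid()]; inferred from `age_midpoint` when `NULL`.
#' @return A [population_hazard()].
#' @export
read_population_hazard <- function(path, grid = NULL) {
  df <- utils::read.csv(path)
  need <- c("age_midpoint", "rate_per_100k", "se_per_100k")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$age_midpoint), ]
  if (is.null(grid)) {
    w <- if (nrow(df) > 1) diff(df$age_midpoint)[1] else 5
    grid <- age_grid(start_age = df$age_midpoint[1] - w / 2, width = w,
                     n_intervals = nrow(df))
  }
  stratum <- if ("stratum" %in% names(df)) df$stratum[1] else "unlabelled"
  population_hazard(df$rate_per_100k, df$se_per_100k, grid = grid,
                    stratum = stratum, per_100k = TRUE)
}

#' Reference pancreatic cancer hazard tables (SEER 9, 1975-2004)
#'
#' Published age-specific hazard-rate estimates of pancreatic cancer
#' occurrence for six population strata, shipped with the package as
#' reference data: the population-level rate with its standard error and
#' the corresponding susceptible-individual rate with its standard error,
#' on the default 14-interval grid (ages 30-99), in cases per 100,000
#' person-years. Cases are first primary, microscopically confirmed
#' pancreatic cancers; "eastern" pools the Atlanta, Connecticut, Detroit and
#' Iowa registries, "western" the Bay area, Seattle, Hawaii, New Mexico and
#' Utah registries.
#'
#' @param stratum One of `"men"`, `"women"`, `"whites"`, `"blacks"`,
#'   `"eastern"`, `"western"`.
#' @return A list with elements `population` (a [population_hazard()]) and
#'   `individual` (an `individual_hazard`, see [invert_hazard()]), both as
#'   published.
#' @examples
#' pc <- pc_hazards("men")
#' pc$population$rate[10] * 1e5  # 9.29 cases per 100,000 person-years
#' @export
pc_hazards <- function(stratum = c("men", "women", "whites", "blacks",
                                   "eastern", "western")) {
  stratum <- match.arg(stratum)
  path <- system.file("extdata", sprintf("pc_%s.csv", stratum),
                      package = "poolhaz", mustWork = TRUE)
  df <- utils::read.csv(path)
  grid <- age_grid()
  pop <- population_hazard(df$pop_rate_per_100k, df$pop_se_per_100k,
                           grid = grid, stratum = stratum)
  ind <- new_individual_hazard(
    theta = df$ind_rate_per_100k / 1e5, se = df$ind_se_per_100k / 1e5,
    grid = grid, stratum = stratum,
    final_bin_flag = TRUE, method = "published", se_method = "published")
  list(population = pop, individual = ind)
}

#' @rdname pc_hazards
#' @format NULL
#' @export
pc_strata <- c("men", "women", "whites", "blacks", "eastern", "western")
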