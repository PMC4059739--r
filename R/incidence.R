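#' Age-by-period incidence table
#'
#' Holds cancer case counts and person-years at risk per age-interval x
#' calendar-period cell, the raw material for age-specific incidence rates.
#'
#' @param cases Integer matrix (`n_intervals` rows x `n_periods` columns) of
#'   case counts; non-negative.
#' @param person_years Numeric matrix of the same shape; strictly positive
#'   person-years at risk per cell.
#' @param grid An [age_grid()] describing the rows.
#' @param period_labels Optional character vector of column labels.
#'
#' @return An object of class `incidence_table`.
#' @seealso [compute_rates()], [pool_periods()], [read_incidence()]
#' @export
incidence_table <- function(cases, person_years, grid = age_grid(),
                            period_labels = NULL) {
  cases <- as.matrix(cases)
  person_years <- as.matrix(person_years)
  stopifnot(is_age_grid(grid))
  if (nrow(cases) != grid$n_intervals)
    stop("`cases` must have one row per age interval (", grid$n_intervals, ")")
  if (!all(dim(cases) == dim(person_years)))
    stop("`cases` and `person_years` must have identical dimensions")
  if (any(cases < 0) || any(cases != round(cases)))
    stop("`cases` must contain non-negative integers")
  bad <- which(!(person_years > 0), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive person-years at cell(s): ",
         paste(sprintf("[%d,%d]", bad[, 1], bad[, 2]), collapse = ", "))
  if (is.null(period_labels)) period_labels <- paste0("period", seq_len(ncol(cases)))
  stopifnot(length(period_labels) == ncol(cases))
  structure(list(cases = unname(cases), person_years = unname(person_years),
                 grid = grid, period_labels = as.character(period_labels)),
            class = "incidence_table")
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("<incidence_table> %d age intervals x %d periods, %d cases total\n",
              nrow(x$cases), ncol(x$cases), sum(x$cases)))
  invisible(x)
}

#' Age-specific incidence rates with Poisson standard errors
#'
#' Converts an incidence table to crude age-specific incidence rates
#' `I = n / N` per cell, with `SE(I) = sqrt(n) / N` from the Poisson model
#' for the case count `n` given person-years `N`. Rates are stored in events
#' per person-year; the conventional "per 100,000" scaling is applied only
#' when writing to file.
#'
#' Zero-count cells get rate 0 and SE 0; such cells carry no weight in
#' inverse-variance pooling (see [pool_periods()]).
#'
#' @param table An [incidence_table()].
#' @return An object of class `rate_table` with matrices `rates` and `ses`
#'   (events per person-year) and the originating `grid`.
#' @examples
#' tab <- incidence_table(matrix(25, 1, 1), matrix(1e6, 1, 1),
#'                        age_grid(n_intervals = 1))
#' rt <- compute_rates(tab)
#' rt$rates * 1e5  # 2.5 cases per 100,000 person-years
#' @export
compute_rates <- function(table) {
  stopifnot(inherits(table, "incidence_table"))
  structure(list(rates = table$cases / table$person_years,
                 ses = sqrt(table$cases) / table$person_years,
                 grid = table$grid, period_labels = table$period_labels),
            class = "rate_table")
}

#' Construct a rate table directly from rates and standard errors
#'
#' For data that arrive as pre-computed rates rather than counts.
#'
#' @param rates,ses Numeric matrices (age intervals x periods), events per
#'   person-year.
#' @param grid An [age_grid()].
#' @param period_labels Optional column labels.
#' @return A `rate_table`.
#' @export
rate_table <- function(rates, ses, grid = age_grid(), period_labels = NULL) {
  rates <- as.matrix(rates); ses <- as.matrix(ses)
  stopifnot(is_age_grid(grid), all(dim(rates) == dim(ses)),
            nrow(rates) == grid$n_intervals,
            all(rates >= 0), all(ses >= 0))
  if (is.null(period_labels)) period_labels <- paste0("period", seq_len(ncol(rates)))
  structure(list(rates = unname(rates), ses = unname(ses), grid = grid,
                 period_labels = as.character(period_labels)),
            class = "rate_table")
}

#' Pool calendar periods into a single population hazard series
#'
#' Collapses the period dimension of a rate table by the inverse-variance
#' weighted mean per age interval, the standard pooling for rates with known
#' standard errors when period and cohort effects are negligible:
#' `lambda_i = sum_j w_j I_ij` with `w_j` proportional to `1 / SE(I_ij)^2`,
#' and `SE(lambda_i) = (sum_j SE(I_ij)^-2)^-1/2`.
#'
#' Zero-count cells (SE = 0) are excluded from the weight sum. If every cell
#' in a row is zero-count the pooled rate and SE are 0 and a warning is
#' issued.
#'
#' @param rates A `rate_table` (from [compute_rates()] or [rate_table()]).
#' @param stratum Label attached to the pooled series.
#' @return A [population_hazard()] object.
#' @export
pool_periods <- function(rates, stratum = "unlabelled") {
  stopifnot(inherits(rates, "rate_table"))
  m <- rates$grid$n_intervals
  lam <- numeric(m); se <- numeric(m)
  empty <- logical(m)
  for (i in seq_len(m)) {
    use <- rates$ses[i, ] > 0
    if (!any(use)) {
      empty[i] <- TRUE
      next
    }
    prec <- 1 / rates$ses[i, use]^2
    lam[i] <- sum(prec * rates$rates[i, use]) / sum(prec)
    se[i] <- 1 / sqrt(sum(prec))
  }
  if (any(empty))
    warning("all-zero-count age row(s) ", paste(which(empty), collapse = ", "),
            ": pooled rate and SE set to 0")
  population_hazard(lam, se, grid = rates$grid, stratum = stratum,
                    per_100k = FALSE)
}

#' Read an age-by-period incidence CSV
#'
#' Expects the flat dialect of SEER*Stat-style exports: columns `age_index`,
#' `age_midpoint`, `period`, `cases`, `person_years`, one row per cell.
#'
#' @param path CSV file path.
#' @param grid Optional [age_grid()]; inferred from `age_midpoint` when `NULL`.
#' @return An [incidence_table()].
#' @export
read_incidence <- function(path, grid = NULL) {
  df <- utils::read.csv(path)
  need <- c("age_index", "age_midpoint", "period", "cases", "person_years")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  idx <- sort(unique(df$age_index))
  if (is.null(grid)) {
    mids <- vapply(idx, function(i) df$age_midpoint[df$age_index == i][1], 0)
    w <- if (length(mids) > 1) diff(mids)[1] else 5
    grid <- age_grid(start_age = mids[1] - w / 2, width = w,
                     n_intervals = length(idx))
  }
  periods <- unique(df$period)
  cases <- matrix(0L, grid$n_intervals, length(periods))
  py <- matrix(NA_real_, grid$n_intervals, length(periods))
  for (k in seq_len(nrow(df))) {
    i <- match(df$age_index[k], idx); j <- match(df$period[k], periods)
    cases[i, j] <- as.integer(df$cases[k]); py[i, j] <- df$person_years[k]
  }
  if (anyNA(py)) stop("incomplete table: some age x period cells are missing")
  incidence_table(cases, py, grid = grid, period_labels = as.character(periods))
}

#' Write an incidence table to CSV in the flat dialect of [read_incidence()]
#' @param x An [incidence_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(x, path) {
  stopifnot(inherits(x, "incidence_table"))
  g <- x$grid
  df <- data.frame(
    age_index = rep(seq_len(g$n_intervals), times = ncol(x$cases)),
    age_midpoint = rep(g$midpoints, times = ncol(x$cases)),
    period = rep(x$period_labels, each = g$n_intervals),
    cases = as.vector(x$cases),
    person_years = as.vector(x$person_years))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a rate table to CSV (rates rendered per 100,000 person-years)
#' @param x A `rate_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(x, path) {
  stopifnot(inherits(x, "rate_table"))
  g <- x$grid
  df <- data.frame(
    age_index = rep(seq_len(g$n_intervals), times = ncol(x$rates)),
    age_midpoint = rep(g$midpoints, times = ncol(x$rates)),
    period = rep(x$period_labels, each = g$n_intervals),
    rate_per_100k = as.vector(x$rates) * 1e5,
    se_per_100k = as.vector(x$ses) * 1e5)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a rate table written by [write_rates()]
#' @param path CSV file path.
#' @param grid Optional [age_grid()]; inferred when `NULL`.
#' @return A `rate_table`.
#' @export
read_rates <- function(path, grid = NULL) {
  df <- utils::read.csv(path)
  need <- c("age_index", "age_midpoint", "period", "rate_per_100k", "se_per_100k")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  idx <- sort(unique(df$age_index))
  if (is.null(grid)) {
    mids <- vapply(idx, function(i) df$age_midpoint[df$age_index == i][1], 0)
    w <- if (length(mids) > 1) diff(mids)[1] else 5
    grid <- age_grid(start_age = mids[1] - w / 2, width = w,
                     n_intervals = length(idx))
  }
  periods <- unique(df$period)
  rates <- matrix(NA_real_, grid$n_intervals, length(periods))
  ses <- matrix(NA_real_, grid$n_intervals, length(periods))
  for (k in seq_len(nrow(df))) {
    i <- match(df$age_index[k], idx); j <- match(df$period[k], periods)
    rates[i, j] <- df$rate_per_100k[k] / 1e5
    ses[i, j] <- df$se_per_100k[k] / 1e5
  }
  if (anyNA(rates)) stop("incomplete table: some age x period cells are missing")
  rate_table(rates, ses, grid = grid, period_labels = as.character(periods))
}
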