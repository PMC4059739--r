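#' Uniform five-year age grid
#'
#' Defines the discrete age axis on which incidence rates and hazard-rate
#' series live: `n_intervals` contiguous, half-open intervals
#' `[a, a + width)` of equal width starting at `start_age`. The default grid
#' (14 five-year intervals from 30 to 100 years) matches the layout of
#' SEER*Stat age-stratified incidence exports for adult cancers.
#'
#' @param start_age Lower bound of the first age interval, in years.
#' @param width Interval width in years.
#' @param n_intervals Number of intervals.
#'
#' @return An object of class `age_grid`: a list with elements `start_age`,
#'   `width`, `n_intervals` and `midpoints` (interval midpoints in years).
#' @examples
#' g <- age_grid()
#' g$midpoints  # 32.5, 37.5, ..., 97.5
#' @export
age_grid <- function(start_age = 30, width = 5, n_intervals = 14) {
  stopifnot(is.numeric(start_age), length(start_age) == 1, is.finite(start_age),
            is.numeric(width), length(width) == 1, width > 0,
            is.numeric(n_intervals), length(n_intervals) == 1, n_intervals >= 1,
            n_intervals == as.integer(n_intervals))
  n_intervals <- as.integer(n_intervals)
  structure(
    list(start_age = start_age, width = width, n_intervals = n_intervals,
         midpoints = start_age + (seq_len(n_intervals) - 1) * width + width / 2),
    class = "age_grid")
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf("<age_grid> %d intervals of %g y: [%g, %g), midpoints %g ... %g\n",
              x$n_intervals, x$width, x$start_age,
              x$start_age + x$n_intervals * x$width,
              x$midpoints[1], x$midpoints[x$n_intervals]))
  invisible(x)
}

is_age_grid <- function(x) inherits(x, "age_grid")

same_grid <- function(a, b) {
  is_age_grid(a) && is_age_grid(b) &&
    a$start_age == b$start_age && a$width == b$width &&
    a$n_intervals == b$n_intervals
}
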