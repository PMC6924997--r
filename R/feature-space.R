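#' Circular stimulus-feature space
#'
#' Defines a 1-D circular feature axis, e.g. visual orientation with period
#' 180 degrees, together with the evaluation grid on which channel basis
#' functions are tabulated.
#'
#' @param period Period of the feature axis in degrees. Orientation is
#'   pi-periodic, hence the default 180.
#' @param n_grid Number of evenly spaced evaluation points in `[0, period)`.
#'   The default 1-degree spacing is fine enough for area-under-curve work
#'   while keeping basis matrices small.
#'
#' @return An object of class `"feature_space"`: a list with elements
#'   `period`, `grid` (evaluation points) and `n_grid`.
#' @examples
#' sp <- feature_space()
#' sp$period
#' @export
feature_space <- function(period = 180, n_grid = 180) {
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0) {
    stop_iemr("iemr_invalid_parameter", "`period` must be a single positive number")
  }
  if (!is.numeric(n_grid) || length(n_grid) != 1L || n_grid < 2 ||
      n_grid != round(n_grid)) {
    stop_iemr("iemr_invalid_parameter", "`n_grid` must be an integer >= 2")
  }
  structure(
    list(period = as.numeric(period),
         grid = period * (seq_len(n_grid) - 1) / n_grid,
         n_grid = as.integer(n_grid)),
    class = "feature_space"
  )
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("Circular feature space: period %g deg, %d grid points (%g deg spacing)\n",
              x$period, x$n_grid, x$period / x$n_grid))
  invisible(x)
}

#' Circular distance between feature values
#'
#' Shortest distance on the circular feature axis; symmetric, bounded by
#' `period / 2`, and invariant to adding multiples of the period to either
#' argument. Vectorized over `a` and `b`.
#'
#' @param a,b Feature values in degrees (recycled to a common length).
#' @param period Period of the axis in degrees, or a [feature_space()] whose
#'   period is used.
#' @return Distances in degrees, in `[0, period / 2]`.
#' @examples
#' circ_dist(0, 170)        # 10: wraps around
#' circ_dist(0, 90)         # 90: maximal for orientation
#' @export
circ_dist <- function(a, b, period = 180) {
  if (inherits(period, "feature_space")) period <- period$period
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

## internal condition-signalling helper: all package errors carry a class so
## callers (and the CLI exit-code contract) can dispatch on them
stop_iemr <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "iemr_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
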