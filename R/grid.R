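#' Discretized distance grid
#'
#' All densities in the observer model (perceived-surface distribution,
#' occlusion prior, disparity likelihood, posterior) live on a uniform 1-D
#' grid of viewing distances. The default spans 0.5–2.5 m in 1 mm steps so
#' every experimental distance (0.9–1.6 m) and the tails of all densities are
#' interior to the grid.
#'
#' @param min_m,max_m Grid bounds in meters; `0 < min_m < max_m`.
#' @param step_m Grid spacing in meters (default 0.001 = 1 mm).
#'
#' @return A numeric vector of grid points (meters) with class
#'   `"distance_grid"` and attribute `step_m`.
#' @examples
#' g <- distance_grid()
#' range(g)
#' grid_step(g)
#' @export
distance_grid <- function(min_m = 0.5, max_m = 2.5, step_m = 0.001) {
  if (!is.finite(min_m) || min_m <= 0) stop("`min_m` must be positive.")
  if (!is.finite(max_m) || max_m <= min_m) stop("`max_m` must exceed `min_m`.")
  if (!is.finite(step_m) || step_m <= 0 || step_m > (max_m - min_m)) {
    stop("`step_m` must be positive and smaller than the grid span.")
  }
  values <- seq(min_m, max_m, by = step_m)
  structure(values, step_m = step_m, class = c("distance_grid", "numeric"))
}

#' @export
print.distance_grid <- function(x, ...) {
  cat(sprintf(
    "<distance_grid> %d points, %.4g–%.4g m, step %.4g m\n",
    length(x), min(x), max(x), grid_step(x)
  ))
  invisible(x)
}

#' Grid spacing
#'
#' @param grid A [distance_grid()].
#' @return The grid step in meters.
#' @export
grid_step <- function(grid) {
  step <- attr(grid, "step_m")
  if (is.null(step)) step <- stats::median(diff(as.numeric(grid)))
  step
}

# Coerce to a validated plain numeric vector of grid points.
as_grid_values <- function(grid) {
  g <- as.numeric(grid)
  if (length(g) < 3) stop("The distance grid needs at least 3 points.")
  d <- diff(g)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-12 * max(abs(g))) {
    stop("Grid points must be strictly increasing and uniformly spaced.")
  }
  g
}

check_in_grid <- function(x, g, what) {
  if (any(x < min(g)) || any(x > max(g))) {
    stop(sprintf("%s must lie within the grid bounds [%g, %g] m.", what, min(g), max(g)))
  }
  invisible(x)
}

#' Normal probability density
#'
#' The Gaussian density `N(x; mu, sigma)` used throughout the observer model
#' (perceived surface location, visibility fall-off, disparity likelihood).
#' A thin validating wrapper around [stats::dnorm()].
#'
#' @param x Evaluation points (meters).
#' @param mu Mean (meters).
#' @param sigma Standard deviation (meters), strictly positive.
#' @return Density values (per meter).
#' @export
gaussian_density <- function(x, mu, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be finite and strictly positive.")
  }
  stats::dnorm(x, mean = mu, sd = sigma)
}
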