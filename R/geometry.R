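#' Visual angle subtended by an object
#'
#' Computes the visual angle (in degrees) subtended by an object of a given
#' physical size viewed frontoparallel at a given distance, using the exact
#' form `2 * atan(size / (2 * distance))` rather than the small-angle
#' approximation.
#'
#' @param physical_size_m Object extent in meters (non-negative).
#' @param distance_m Viewing distance in meters (strictly positive).
#'
#' @return Visual angle in degrees. Vectorized over both arguments.
#'
#' @examples
#' # A 5.65 cm letter at the nearest and farthest test distances
#' visual_angle_deg(0.0565, c(0.9, 1.6))
#' @seealso [physical_size_for_angle()] for the inverse.
#' @export
visual_angle_deg <- function(physical_size_m, distance_m) {
  if (any(!is.finite(distance_m)) || any(distance_m <= 0)) {
    stop("`distance_m` must be finite and strictly positive.")
  }
  if (any(!is.finite(physical_size_m)) || any(physical_size_m < 0)) {
    stop("`physical_size_m` must be finite and non-negative.")
  }
  2 * atan(physical_size_m / (2 * distance_m)) * 180 / pi
}

#' Physical size needed to subtend a given visual angle
#'
#' Inverse of [visual_angle_deg()]: the frontoparallel extent (meters) that
#' subtends `angular_size_deg` at `distance_m`, i.e.
#' `2 * distance * tan(angle / 2)`. Used to scale a stimulus with distance so
#' its retinal size stays constant.
#'
#' @param angular_size_deg Visual angle in degrees, in (0, 180).
#' @param distance_m Viewing distance in meters (strictly positive).
#'
#' @return Physical size in meters. Vectorized.
#' @export
physical_size_for_angle <- function(angular_size_deg, distance_m) {
  if (any(!is.finite(distance_m)) || any(distance_m <= 0)) {
    stop("`distance_m` must be finite and strictly positive.")
  }
  if (any(!is.finite(angular_size_deg)) ||
      any(angular_size_deg <= 0) || any(angular_size_deg >= 180)) {
    stop("`angular_size_deg` must lie strictly between 0 and 180 degrees.")
  }
  2 * distance_m * tan(angular_size_deg * pi / 360)
}

#' Michelson contrast
#'
#' `(l_max - l_min) / (l_max + l_min)`, the standard photometric contrast
#' measure, used here to quantify the opacity of the occluding surface from
#' luminance readings taken through it.
#'
#' @param l_max Maximum luminance (cd/m^2), `>= l_min`.
#' @param l_min Minimum luminance (cd/m^2), non-negative.
#'
#' @return Contrast in \[0, 1\]. Vectorized.
#' @export
michelson_contrast <- function(l_max, l_min) {
  if (any(!is.finite(l_max)) || any(!is.finite(l_min)) || any(l_min < 0)) {
    stop("Luminances must be finite and non-negative.")
  }
  if (any(l_min > l_max)) {
    stop("`l_min` must not exceed `l_max`.")
  }
  if (any(l_max + l_min == 0)) {
    stop("At least one luminance must be positive.")
  }
  (l_max - l_min) / (l_max + l_min)
}

#' Round half away from zero
#'
#' Report-level rounding used for printed stimulus values (e.g. angular sizes
#' to one decimal). Unlike [base::round()]'s round-half-even, 0.05 rounds up
#' to 0.1. Raw computations in this package never round; this is applied only
#' when formatting values for report-style comparison.
#'
#' @param x Numeric vector (non-negative quantities such as angles or
#'   distances).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Stimulus geometry table for an experimental design
#'
#' Tabulates, per target distance, the physical and angular size of the
#' stimulus implied by the design's size mode: under `constant_angle` the
#' physical size is scaled with distance to hold the visual angle fixed;
#' under `constant_physical` the angular size shrinks with distance.
#'
#' @param design An [experiment_design()] / [make_design()] object.
#'
#' @return A tibble with columns `target_distance_m`, `physical_size_m`,
#'   `angular_size_deg`.
#' @examples
#' describe_design(make_design("exp2"))
#' @export
describe_design <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  d <- design$target_distances_m
  if (design$size_mode == "constant_angle") {
    phys <- physical_size_for_angle(design$angular_size_deg, d)
    ang <- rep(design$angular_size_deg, length(d))
  } else {
    phys <- rep(design$physical_size_m, length(d))
    ang <- visual_angle_deg(design$physical_size_m, d)
  }
  tibble::tibble(
    target_distance_m = d,
    physical_size_m = phys,
    angular_size_deg = ang
  )
}
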