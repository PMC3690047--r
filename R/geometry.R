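#' Distance-invariant projected area
#'
#' A segmented object of `a_CI` pixels at depth `Z` shrinks quadratically
#' with distance; rescaling by `Z^2 / f^2` gives a quantity
#' `t = a_CI * Z^2 / f^2` that is independent of the camera-object distance
#' (the image-inversion sign of the projection is dropped: areas are
#' magnitudes).
#'
#' @param a_CI Segmented object area in pixels (squared pixels).
#' @param Z Depth in cm.
#' @param f_px Focal length in pixels.
#' @return The distance-invariant area `t`.
#' @export
distance_invariant_area <- function(a_CI, Z, f_px) {
  stopifnot(all(a_CI >= 0), all(Z > 0), all(f_px > 0))
  a_CI * Z^2 / f_px^2
}

#' Stored bench calibration of the pixel-area to cm^2 conversion
#'
#' Coefficients of the cubic (in increasing powers of `t`) fitted on the
#' original bench camera against circles of known size; the constant term
#' is read as -3.95e-1. For an ideal distortion-free pin-hole camera the
#' identity conversion `c(0, 1)` applies instead.
#'
#' @format Numeric vector `c(a0, a1, a2, a3)`.
#' @export
eq_area_default_coefficients <- c(-3.95e-1, 2.05e-3, 1.11e-7, -4.45e-12)

#' Convert distance-invariant area to cm^2
#'
#' Polynomial conversion from the distance-invariant pixel area `t` to
#' physical area, calibrated on circles of known size. The default
#' coefficients are the stored bench calibration (a cubic in `t`); a
#' different calibration (e.g. from [fit_area_calibration()]) can be passed
#' for other cameras. Raw negative predictions near t = 0 are clamped to 0
#' and flagged.
#'
#' @param t Distance-invariant area from [distance_invariant_area()].
#' @param coefficients Polynomial coefficients in increasing powers of `t`.
#' @return List with `area_cm2` (clamped at 0), `raw` (unclamped) and
#'   logical `clamped`.
#' @export
area_to_cm2 <- function(t, coefficients = eq_area_default_coefficients) {
  stopifnot(all(t >= 0), length(coefficients) >= 2)
  raw <- rowSums(outer(t, seq_along(coefficients) - 1, `^`) *
                   rep(coefficients, each = length(t)))
  list(area_cm2 = pmax(0, raw), raw = raw, clamped = raw < 0)
}

#' Fit a pixel-area to physical-area calibration
#'
#' Mirrors the bench procedure behind the stored conversion: given circles
#' of known physical area and their measured distance-invariant pixel areas,
#' fit a least-squares polynomial (degree 2 by default) mapping `t` to cm^2.
#'
#' @param t Measured distance-invariant areas.
#' @param area_cm2 True physical areas, cm^2.
#' @param degree Polynomial degree (default 2).
#' @return Coefficient vector in increasing powers of `t`, usable as the
#'   `coefficients` argument of [area_to_cm2()].
#' @export
fit_area_calibration <- function(t, area_cm2, degree = 2) {
  stopifnot(length(t) == length(area_cm2), length(t) > degree)
  fit <- stats::lm(area_cm2 ~ stats::poly(t, degree, raw = TRUE))
  unname(stats::coef(fit))
}

#' Radius and volume of a sphere from its projected area
#'
#' Under the spherical-fruit assumption the segmented projection is a circle
#' of area `A = pi r^2`, so `r = sqrt(A / pi)` and the fruit volume is
#' `V = (4/3) pi r^3`.
#'
#' @param A Projected physical area in cm^2 (>= 0).
#' @return `radius_from_area`: radius in cm. `sphere_volume`: volume in cm^3.
#' @export
radius_from_area <- function(A) {
  if (any(A < 0)) stop("area must be non-negative")
  sqrt(A / pi)
}

#' @rdname radius_from_area
#' @export
sphere_volume <- function(A) {
  r <- radius_from_area(A)
  (4 / 3) * pi * r^3
}
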