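#' Pressure from the fingertip probe's pressure transducer
#'
#' Converts the output voltage of the MPX5700-style pressure transducer used
#' behind the fingertip probe into pressure. The transfer function is the
#' manufacturer's: the voltage above the offset is divided by the sensor
#' sensitivity (0.064290 V per unit) and scaled by 0.101972, the constant
#' converting kPa to kgf/cm^2.
#'
#' @param X Sensor output tension in volts.
#' @param A Offset voltage; typically 0.2 V.
#' @return Pressure in kgf/cm^2. Negative values are returned unclamped
#'   (readings below the offset); the caller interprets them.
#' @examples
#' transducer_pressure(0.264290) # one sensitivity step above offset
#' @export
transducer_pressure <- function(X, A = 0.2) {
  stopifnot(is.numeric(X), all(is.finite(X)), is.numeric(A), all(is.finite(A)))
  ((X - A) / 0.064290) * 0.101972
}

#' Fingertip pressure from the calibrated probe
#'
#' Linear calibration of the whole probe assembly (chamber, tube and
#' transducer) against a reference gauge: P = 0.83 P0 - 0.02.
#'
#' @param P0 Transducer pressure in kgf/cm^2 (see [transducer_pressure()]).
#' @return Probe pressure in kgf/cm^2; may be slightly negative near zero
#'   because the fitted intercept is negative.
#' @export
probe_pressure <- function(P0) {
  stopifnot(is.numeric(P0), all(is.finite(P0)))
  0.83 * P0 - 0.02
}

#' Fingertip pressure from a force sensitive resistor
#'
#' FSR resistance falls with applied force following an inverse power law;
#' the calibrated power-form transfer function is P = 3.29 x^-2.061 with x
#' the divider tension in volts. A degree-2 polynomial alternative
#' (P = 0.0802 x^2 - 0.77 x + 2.606) is kept for comparison; the power form
#' fits FSR physics better and is the default.
#'
#' @param x Sensor tension in volts.
#' @param form `"power"` (default) or `"poly2"`.
#' @return Pressure in kgf/cm^2.
#' @export
fsr_pressure <- function(x, form = c("power", "poly2")) {
  form <- match.arg(form)
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (form == "power") {
    if (any(x <= 0)) {
      stop("power-form FSR calibration requires positive tension x")
    }
    3.29 * x^(-2.061)
  } else {
    0.0802 * x^2 - 0.77 * x + 2.606
  }
}

#' Distance from the infrared proximity sensor
#'
#' The IR sensor's voltage is a non-linear function of distance; the fitted
#' power regression is D = 2736.24 adc^-0.9909 with `adc` the raw 10-bit
#' reading. The sensor gates the optical pipeline: vision runs only when an
#' object sits in its 5-25 cm activation range.
#'
#' @param adc Raw ADC reading (> 0).
#' @return A list with `distance_cm` and `in_activation_range`
#'   (TRUE when 5 cm <= D <= 25 cm).
#' @export
ir_distance <- function(adc) {
  stopifnot(is.numeric(adc), all(is.finite(adc)))
  if (any(adc <= 0)) stop("IR distance requires adc > 0")
  d <- 2736.24 * adc^(-0.9909)
  list(distance_cm = d, in_activation_range = d >= 5 & d <= 25)
}

#' Finger flexion angle from a bend-sensor reading
#'
#' Linear map between the ADC readings recorded with the hand completely
#' closed and completely opened. The angular endpoints are a convention
#' (the hardware only defines the two reference postures); the default sends
#' closed to 0 degrees and open to 180 degrees. Output is clamped to the
#' endpoint interval.
#'
#' @param raw Raw ADC reading.
#' @param closed_ref,open_ref ADC readings at the closed / open postures.
#' @param closed_deg,open_deg Angles assigned to the two postures.
#' @return Angle in degrees.
#' @export
bend_to_angle <- function(raw, closed_ref, open_ref,
                          closed_deg = 0, open_deg = 180) {
  stopifnot(is.numeric(raw), is.numeric(closed_ref), is.numeric(open_ref))
  if (closed_ref == open_ref) {
    stop("closed and open reference readings must differ")
  }
  frac <- (raw - closed_ref) / (open_ref - closed_ref)
  ang <- closed_deg + frac * (open_deg - closed_deg)
  pmin(max(closed_deg, open_deg), pmax(min(closed_deg, open_deg), ang))
}

#' Convert kgf/cm^2 (technical atmosphere) to kPa
#'
#' The fingertip calibrations are expressed in kgf/cm^2 while turgor
#' thresholds are quoted in kPa; 1 kgf/cm^2 = 98.0665 kPa exactly.
#'
#' @param p Pressure in kgf/cm^2.
#' @return Pressure in kPa.
#' @export
kgfcm2_to_kpa <- function(p) p * 98.0665

#' @rdname kgfcm2_to_kpa
#' @param kpa Pressure in kPa.
#' @export
kpa_to_kgfcm2 <- function(kpa) kpa / 98.0665
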