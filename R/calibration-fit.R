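#' Construct a calibration model object
#'
#' A `calibration_model` holds a fitted sensor transfer function: its
#' functional form, coefficients (or spline knots), unit tags, goodness of
#' fit on the original scale, and the raw-reading span it was fitted over.
#'
#' @param form One of `"linear"`, `"poly2"`, `"power"`, `"spline"`.
#' @param coefficients For `linear`: c(slope, intercept); for `poly2`:
#'   c(a2, a1, a0); for `power` (y = a x^b): c(a, b). Ignored for splines.
#' @param knots For `form = "spline"`, a data.frame with columns `x`, `y`.
#' @param input_units,output_units Free-text unit tags.
#' @param r_squared Coefficient of determination in `[0, 1]`.
#' @param valid_range Numeric length-2, the observed raw-reading span.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(form, coefficients = NULL, knots = NULL,
                              input_units = "", output_units = "",
                              r_squared = NA_real_, valid_range = NULL) {
  form <- match.arg(form, c("linear", "poly2", "power", "spline"))
  n_expected <- c(linear = 2L, poly2 = 3L, power = 2L)
  if (form == "spline") {
    stopifnot(is.data.frame(knots), nrow(knots) >= 3,
              all(c("x", "y") %in% names(knots)))
    if (is.null(valid_range)) valid_range <- range(knots$x)
  } else {
    stopifnot(length(coefficients) == n_expected[[form]],
              all(is.finite(coefficients)))
  }
  if (!is.na(r_squared)) stopifnot(r_squared >= 0, r_squared <= 1)
  stopifnot(length(valid_range) == 2, valid_range[1] < valid_range[2])
  structure(
    list(form = form, coefficients = unname(coefficients), knots = knots,
         input_units = input_units, output_units = output_units,
         r_squared = r_squared, valid_range = as.numeric(valid_range)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>", x$form, "\n")
  if (x$form == "spline") {
    cat("  knots:", nrow(x$knots), "\n")
  } else {
    cat("  coefficients:", signif(x$coefficients, 6), "\n")
  }
  cat("  units:", x$input_units, "->", x$output_units, "\n")
  if (!is.na(x$r_squared)) cat("  r^2:", signif(x$r_squared, 4), "\n")
  cat("  valid range:", x$valid_range[1], "-", x$valid_range[2], "\n")
  invisible(x)
}

#' Evaluate a calibration model
#'
#' @param model A `calibration_model`.
#' @param x Raw readings.
#' @return Predicted reference quantity in `model$output_units`.
#' @export
predict_calibration <- function(model, x) {
  stopifnot(inherits(model, "calibration_model"))
  cf <- model$coefficients
  switch(model$form,
    linear = cf[1] * x + cf[2],
    poly2  = cf[1] * x^2 + cf[2] * x + cf[3],
    power  = cf[1] * x^cf[2],
    spline = stats::splinefun(model$knots$x, model$knots$y,
                              method = "natural")(x)
  )
}

r_squared_original_scale <- function(y, yhat) {
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  max(0, min(1, 1 - ss_res / ss_tot))
}

#' Fit a sensor transfer function to calibration pairs
#'
#' Least-squares fit of a linear, degree-2 polynomial or power-law transfer
#' function to `(x_raw, y_ref)` calibration pairs, mirroring the bench
#' procedure of pressing known reference values while logging the sensor.
#' Power laws are fitted by ordinary least squares on the log-log scale
#' (the standard "power regression"); r^2 is always reported on the
#' original scale so forms are comparable.
#'
#' @param pairs A data.frame with columns `x_raw`, `y_ref`.
#' @param form `"linear"`, `"poly2"` or `"power"`.
#' @param input_units,output_units Unit tags stored on the model.
#' @return A [calibration_model()].
#' @export
fit_model <- function(pairs, form = c("linear", "poly2", "power"),
                      input_units = "", output_units = "") {
  form <- match.arg(form)
  stopifnot(is.data.frame(pairs), all(c("x_raw", "y_ref") %in% names(pairs)))
  x <- pairs$x_raw
  y <- pairs$y_ref
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n_min <- c(linear = 2L, poly2 = 3L, power = 2L)[[form]]
  if (nrow(pairs) < n_min) stop("too few calibration pairs for form ", form)
  if (length(unique(x)) < n_min) stop("degenerate calibration pairs")

  cf <- switch(form,
    linear = {
      fit <- stats::lm(y ~ x)
      c(unname(stats::coef(fit))[2], unname(stats::coef(fit))[1])
    },
    poly2 = {
      fit <- stats::lm(y ~ x + I(x^2))
      b <- unname(stats::coef(fit))
      c(b[3], b[2], b[1])
    },
    power = {
      if (any(x <= 0) || any(y <= 0)) {
        stop("power fit requires positive x_raw and y_ref")
      }
      fit <- stats::lm(log(y) ~ log(x))
      b <- unname(stats::coef(fit))
      c(exp(b[1]), b[2])
    }
  )
  model <- calibration_model(form, cf,
                             input_units = input_units,
                             output_units = output_units,
                             valid_range = range(x))
  model$r_squared <- r_squared_original_scale(y, predict_calibration(model, x))
  model
}

#' Fit the finger-bend spline for sphere diameter
#'
#' Passes a natural cubic interpolating spline through (raw ADC reading,
#' sphere diameter) calibration points, so that a finger wrapped around a
#' sphere of unknown size maps its bend reading to a diameter. The spline
#' passes exactly through every knot.
#'
#' @param pairs data.frame with columns `x_raw` (strictly monotone ADC
#'   readings) and `y_ref` (reference diameters, mm).
#' @return A `calibration_model` with `form = "spline"`.
#' @export
fit_bend_spline <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("x_raw", "y_ref") %in% names(pairs)),
            nrow(pairs) >= 3)
  d <- diff(pairs$x_raw)
  if (!(all(d > 0) || all(d < 0))) {
    stop("bend-spline calibration requires strictly monotone x_raw")
  }
  ord <- order(pairs$x_raw)
  knots <- data.frame(x = pairs$x_raw[ord], y = pairs$y_ref[ord])
  model <- calibration_model("spline", knots = knots,
                             input_units = "adc", output_units = "mm",
                             valid_range = range(knots$x))
  model$r_squared <- 1  # interpolant: zero residual at knots
  model
}

#' Sphere diameter from a finger-bend reading
#'
#' Evaluates the bend-calibration spline at a raw ADC reading. Readings
#' outside the calibrated span are clamped to it and flagged, since the
#' spline has no support for extrapolation.
#'
#' @param model A spline `calibration_model` from [fit_bend_spline()].
#' @param raw Raw 10-bit ADC readings.
#' @return List with `diameter_mm` and logical `extrapolated`.
#' @export
bend_to_diameter <- function(model, raw) {
  stopifnot(inherits(model, "calibration_model"), model$form == "spline")
  lo <- model$valid_range[1]
  hi <- model$valid_range[2]
  outside <- raw < lo | raw > hi
  if (any(outside)) {
    warning("bend reading outside calibrated range; clamped")
  }
  list(diameter_mm = predict_calibration(model, pmin(hi, pmax(lo, raw))),
       extrapolated = outside)
}

#' Read calibration pairs from CSV
#'
#' @param path CSV file with header `x_raw,y_ref`.
#' @return data.frame of calibration pairs.
#' @export
read_calibration_pairs <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_raw", "y_ref") %in% names(df))) {
    stop("calibration CSV must have columns x_raw,y_ref")
  }
  df
}

#' Serialize / deserialize a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path Output/input JSON path.
#' @return `read_calibration_model` returns a `calibration_model`.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(
    form = obj$form,
    coefficients = obj$coefficients,
    knots = if (!is.null(obj$knots)) as.data.frame(obj$knots),
    input_units = obj$input_units %||% "",
    output_units = obj$output_units %||% "",
    r_squared = obj$r_squared %||% NA_real_,
    valid_range = obj$valid_range
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
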