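#' Reference calibration points for the finger-bend sphere-diameter spline
#'
#' Raw 10-bit bend-sensor readings recorded while the gloved finger wrapped
#' reference spheres of known diameter. These four points are the knots of
#' the diameter spline fitted by [fit_bend_spline()]; the reading falls as
#' the sphere grows because a larger sphere straightens the finger.
#'
#' @return data.frame with columns `x_raw` (ADC reading) and `y_ref`
#'   (sphere diameter, mm).
#' @export
bend_reference_pairs <- function() {
  data.frame(x_raw = c(887, 859, 826, 809),
             y_ref = c(25, 50, 100, 150))
}

#' Bench measurements of sphere diameters through the bend spline
#'
#' Sensor readings taken while the glove touched spheres of known diameter,
#' with the diameter the spline calibration should report. Useful as a
#' worked validation set for [bend_to_diameter()].
#'
#' @return data.frame with columns `reading`, `computed_mm` (value the
#'   bench system reported) and `ground_truth_mm`.
#' @export
bend_validation_table <- function() {
  data.frame(
    reading = c(872, 860, 862, 870, 865, 844, 842, 825, 812),
    computed_mm = c(37.98, 49.03, 47.13, 39.77, 44.32, 66.73, 69.51,
                    102.51, 146.49),
    ground_truth_mm = c(35, 50, 50, 40, 45, 65, 70, 100, 150)
  )
}

#' Reference turgor-pressure summaries for six climacteric fruits
#'
#' Bench summaries (mean of 30 repeated glove measurements, extrema and
#' sample standard deviation) of turgor pressure for four specimens each of
#' six climacteric fruits, from most unripe (fruit 1) to most ripe
#' (fruit 4). Used as realistic regimes for the trace simulator and as
#' worked examples for [classify_ripeness()].
#'
#' @return data.frame with columns `fruit`, `specimen`, `average_kPa`,
#'   `max_kPa`, `min_kPa`, `sd_kPa`.
#' @export
fruit_turgor_reference <- function() {
  data.frame(
    fruit = rep(c("tomato", "pear", "banana", "papaya", "guava", "mango"),
                each = 4),
    specimen = rep(1:4, times = 6),
    average_kPa = c(272, 249, 129, 63,
                    269, 179, 156, 85,
                    132, 86, 62, 57,
                    257, 186, 73, 54,
                    267, 222, 161, 81,
                    259, 158, 85, 70),
    max_kPa = c(275, 255, 133, 64,
                275, 206, 165, 88,
                138, 94, 62, 59,
                267, 217, 81, 55,
                267, 248, 177, 83,
                263, 168, 87, 72),
    min_kPa = c(271, 241, 126, 63,
                267, 154, 147, 82,
                121, 76, 61, 52,
                204, 142, 65, 53,
                267, 196, 137, 80,
                259, 141, 83, 70),
    sd_kPa = c(1.7, 3.5, 1.7, 0.5,
               2.3, 11.2, 5.5, 1.8,
               4.4, 4.4, 0.3, 1.4,
               18.1, 19.6, 3.8, 0.5,
               0, 16.1, 10.4, 0.7,
               0.7, 6.7, 1.1, 0.5)
  )
}
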