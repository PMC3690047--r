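#' Multi-finger grasp pressure traces
#'
#' A `grasp_trace` holds synchronized per-finger fingertip pressure
#' channels, already converted to kPa, plus the sample rate.
#'
#' @param channels Named list (or data.frame) of equal-length numeric
#'   pressure vectors, one per finger, in kPa.
#' @param sample_rate_hz Samples per second.
#' @return A `grasp_trace` object.
#' @export
grasp_trace <- function(channels, sample_rate_hz) {
  channels <- as.data.frame(channels)
  stopifnot(ncol(channels) >= 1, nrow(channels) >= 1, sample_rate_hz > 0)
  if (any(as.matrix(channels) < 0)) {
    stop("pressures must be non-negative after unit conversion")
  }
  structure(list(channels = channels, sample_rate_hz = sample_rate_hz),
            class = "grasp_trace")
}

#' Read a grasp trace from CSV
#'
#' Expected columns: `t_s` (time in seconds) followed by one pressure column
#' per finger. Pressures are taken as kPa unless a `calibration` model is
#' given, in which case columns are raw sensor tensions converted through it
#' (and then kgf/cm^2 to kPa).
#'
#' @param path CSV path.
#' @param calibration Optional [calibration_model()] applied to raw columns.
#' @return A [grasp_trace()].
#' @export
read_grasp_trace <- function(path, calibration = NULL) {
  df <- utils::read.csv(path)
  if (!"t_s" %in% names(df)) stop("trace CSV must have a t_s column")
  t <- df$t_s
  if (length(t) < 2) stop("trace too short")
  rate <- 1 / stats::median(diff(t))
  ch <- df[setdiff(names(df), "t_s")]
  if (!is.null(calibration)) {
    ch[] <- lapply(ch, function(v) {
      pmax(0, kgfcm2_to_kpa(predict_calibration(calibration, v)))
    })
  }
  grasp_trace(ch, rate)
}

#' Detect grasp events in a pressure trace
#'
#' Each fruit grasp shows as a pressure pulse held for a few seconds. An
#' event spans every maximal run of samples where the maximum pressure
#' across fingers exceeds `on_kPa`, kept only if it lasts at least
#' `min_duration_s`. The per-finger plateau statistic is the median over the
#' middle 80% of the event (trimming the rise and release ramps).
#'
#' @param trace A [grasp_trace()].
#' @param on_kPa Detection threshold in kPa (> 0).
#' @param min_duration_s Minimum event duration in seconds.
#' @param valid_ratio Passed to [valid_fingers()].
#' @return List of `grasp_event`s, each with `start`, `end` (half-open
#'   sample indices, 1-based start), `plateaus_kPa` (named per finger),
#'   `valid_fingers`, and `pressure_kPa` (mean of valid-finger plateaus).
#' @export
detect_grasps <- function(trace, on_kPa = 20, min_duration_s = 1,
                          valid_ratio = 0.5) {
  stopifnot(inherits(trace, "grasp_trace"), on_kPa > 0)
  M <- as.matrix(trace$channels)
  if (nrow(M) == 0) stop("empty trace")
  env <- apply(M, 1, max)
  on <- env > on_kPa
  if (!any(on)) return(list())
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  min_len <- ceiling(min_duration_s * trace$sample_rate_hz)
  keep <- r$values & r$lengths >= min_len
  events <- lapply(which(keep), function(k) {
    s <- starts[k]; e <- ends[k]
    n <- e - s + 1
    trim <- floor(n * 0.1)
    mid <- (s + trim):(e - trim)
    plateaus <- apply(M[mid, , drop = FALSE], 2, stats::median)
    ev <- structure(
      list(start = s, end = e + 1L, plateaus_kPa = plateaus,
           valid_fingers = character(), pressure_kPa = NA_real_),
      class = "grasp_event"
    )
    vf <- valid_fingers(ev, ratio = valid_ratio)
    ev$valid_fingers <- vf
    ev$pressure_kPa <- mean(plateaus[vf])
    ev
  })
  events
}

#' Fingers whose measurement should be kept for a grasp
#'
#' Fingers that did not cooperate with the grasp show markedly lower
#' plateau pressure and must be ignored. A finger is valid when its plateau
#' is at least `ratio` times the largest finger plateau of the event.
#'
#' @param event A `grasp_event`.
#' @param ratio Fraction of the maximum plateau (default 0.5), in (0, 1].
#' @return Character vector of valid finger names.
#' @export
valid_fingers <- function(event, ratio = 0.5) {
  stopifnot(ratio > 0, ratio <= 1)
  p <- event$plateaus_kPa
  names(p)[p >= ratio * max(p)]
}

#' Classify fruit ripeness from turgor pressure
#'
#' Turgor pressure (the pressure difference between cell interior and the
#' barometric pressure) is a firmness proxy: ripe fruit sit at 20-100 kPa,
#' unripe at 150-400 kPa, and readings close to zero indicate fruit
#' inadequate for consumption. The band between 100 and 150 kPa, not
#' assigned by those ranges, is reported as "ripening"; readings above
#' 400 kPa remain "unripe" but are flagged out of the documented range.
#'
#' @param p_kPa Turgor pressure in kPa (>= 0).
#' @return Factor with levels `inadequate < ripe < ripening < unripe`.
#'   Attribute `out_of_range` flags readings above 400 kPa.
#' @export
classify_ripeness <- function(p_kPa) {
  if (any(p_kPa < 0)) stop("turgor pressure must be non-negative")
  cls <- ifelse(p_kPa < 20, "inadequate",
         ifelse(p_kPa <= 100, "ripe",
         ifelse(p_kPa < 150, "ripening", "unripe")))
  out <- factor(cls, levels = c("inadequate", "ripe", "ripening", "unripe"),
                ordered = TRUE)
  attr(out, "out_of_range") <- p_kPa > 400
  out
}

#' Summary statistics of repeated turgor measurements
#'
#' @param values Numeric vector of pressures (kPa), length >= 2.
#' @return List: `average`, `max`, `min`, `sd` (sample standard deviation),
#'   `n`.
#' @export
summarize_measurements <- function(values) {
  if (length(values) < 2) stop("need at least 2 measurements")
  list(average = mean(values), max = max(values), min = min(values),
       sd = stats::sd(values), n = length(values))
}

#' Triangular membership of a feature in its ideal range
#'
#' Maps a raw feature value into `[0, 1]`: 1 at the centre of the
#' configured ideal range, falling linearly to 0 at the range limits and
#' staying 0 outside.
#'
#' @param x Feature value.
#' @param lo,hi Configured limits; membership is 0 at and beyond them.
#' @return Membership in `[0, 1]`.
#' @export
triangular_membership <- function(x, lo, hi) {
  stopifnot(hi > lo)
  c0 <- (lo + hi) / 2
  half <- (hi - lo) / 2
  pmax(0, 1 - abs(x - c0) / half)
}

#' Weighted fruit quality score and alert
#'
#' Combines per-feature memberships into one quality number: each feature is
#' normalized to `[0, 1]` by a triangular membership over its user-supplied
#' ideal range, then averaged with user weights. The score is invariant to
#' uniform weight rescaling. An alert is raised when the score falls below
#' a customizable threshold (on the physical glove this drives the
#' vibration motor).
#'
#' @param features Named numeric vector of measured features.
#' @param weights Named non-negative weights (same names; sum > 0).
#' @param ranges Named list of `c(lo, hi)` ideal ranges per feature.
#' @return Score in `[0, 1]`.
#' @export
quality_score <- function(features, weights, ranges) {
  stopifnot(length(features) > 0,
            all(names(features) %in% names(weights)),
            all(names(features) %in% names(ranges)))
  w <- weights[names(features)]
  stopifnot(all(w >= 0), sum(w) > 0)
  memb <- vapply(names(features), function(f) {
    triangular_membership(features[[f]], ranges[[f]][1], ranges[[f]][2])
  }, numeric(1))
  sum(w * memb) / sum(w)
}

#' @rdname quality_score
#' @param score A quality score in `[0, 1]`.
#' @param threshold Alert threshold (default 0.5).
#' @return `quality_alert`: TRUE when the score is below the threshold.
#' @export
quality_alert <- function(score, threshold = 0.5) score < threshold
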