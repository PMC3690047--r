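#' Default pipeline configuration
#'
#' A nested list of every tunable the measure pipeline uses: camera block,
#' segmentation parameters, depth-source working ranges, the pixel->cm^2
#' area conversion, and grading weights/ranges. [read_pipeline_config()]
#' loads a YAML file with the same structure and validates it against this
#' template (unknown keys are rejected).
#'
#' @return Named list of configuration blocks.
#' @export
default_pipeline_config <- function() {
  list(
    camera = list(width_px = 320, height_px = 240, fov_deg = NULL,
                  f_px = 100, baseline_H_cm = 1.0),
    segmentation = list(theta = 0.7, sigma = 25, ttl_init = 30,
                        dot_score_threshold = 60, dot_min_brightness = 200),
    depth = list(laser_range_cm = c(3, 7.3), ir_range_cm = c(5, 25)),
    # identity conversion: for an ideal (distortion-free) pin-hole camera
    # the distance-invariant area a_CI * Z^2 / f^2 is already in cm^2. The
    # bench camera's calibrated cubic (eq_area_default_coefficients) or a
    # fit from fit_area_calibration() replaces it for real optics.
    area_model = list(coefficients = c(0, 1)),
    grading = list(on_kPa = 20, min_duration_s = 1, valid_ratio = 0.5,
                   alert_threshold = 0.5,
                   weights = list(pressure_kPa = 1),
                   ranges = list(pressure_kPa = c(20, 100)))
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base)) {
      stop("unknown configuration key: ", paste0(path, k))
    }
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], as.list(user[[k]]),
                                paste0(path, k, "$"))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' @rdname default_pipeline_config
#' @param path YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_pipeline_config(), user)
  stopifnot(cfg$segmentation$theta > 0, cfg$segmentation$theta <= 1,
            cfg$segmentation$sigma > 0, cfg$grading$on_kPa > 0)
  cfg
}

config_camera <- function(cfg) {
  cc <- cfg$camera
  camera_model(width_px = cc$width_px, height_px = cc$height_px,
               fov_deg = if (is.null(cc$f_px)) cc$fov_deg else 48,
               f_px = cc$f_px, baseline_H_cm = cc$baseline_H_cm)
}

#' Measure a fruit end-to-end
#'
#' Chains the full grading pipeline: IR distance gating, laser-dot
#' detection, seeding and fuzzy segmentation, distance-invariant area,
#' spherical radius/volume, grasp detection and turgor classification, and
#' the weighted quality score with its alert. Depth sources are prioritised
#' laser (within its working range) > IR sensor (within its activation
#' range) > stereo, the laser being the most precise at close range.
#'
#' Geometry fields are filled only when an image with a detectable dot is
#' supplied (and the distance gate passes); pressure fields only when a
#' trace is supplied. At least one of the two inputs is required.
#'
#' @param image Path to a PNG or an HxWx3 array (0-255); optional.
#' @param trace A [grasp_trace()] or path to a trace CSV; optional.
#' @param config Configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file.
#' @param ir_adc Optional raw IR distance-sensor reading used for the
#'   activation gate and as a fallback depth source.
#' @return A `fruit_report` list: `pressure_kPa`, `ripeness`, `area_cm2`,
#'   `radius_cm`, `volume_cm3`, `depth` (source, Z, reliability),
#'   `quality_score`, `alert`, plus a `log` of parameters used.
#' @export
run_measure <- function(image = NULL, trace = NULL,
                        config = default_pipeline_config(),
                        ir_adc = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(image) && is.null(trace)) {
    stop("run_measure needs an image or a pressure trace")
  }
  cam <- config_camera(config)
  report <- list(
    schema_version = 1L,
    pressure_kPa = NULL, ripeness = NULL,
    area_cm2 = NULL, radius_cm = NULL, volume_cm3 = NULL,
    depth = NULL, quality_score = NULL, alert = FALSE,
    units = list(pressure = "kPa", area = "cm2", radius = "cm",
                 volume = "cm3"),
    log = list(config = config)
  )

  gate_open <- TRUE
  ir_est <- NULL
  if (!is.null(ir_adc)) {
    d <- ir_distance(ir_adc)
    gate_open <- d$in_activation_range
    if (gate_open) ir_est <- depth_estimate(d$distance_cm, "ir_sensor")
    report$log$ir_distance_cm <- d$distance_cm
  }

  if (!is.null(image) && gate_open) {
    img <- if (is.character(image)) read_image(image) else image
    sg <- config$segmentation
    dot <- detect_laser_dot(img, sg$dot_score_threshold,
                            sg$dot_min_brightness)
    if (is.null(dot) && is.null(trace)) {
      stop("no laser dot detected and no trace supplied")
    }
    if (!is.null(dot)) {
      fine <- refine_dot(img, dot, score_threshold = sg$dot_score_threshold)
      offset <- abs(fine[["x"]] - cam$cx)
      est <- NULL
      if (offset > 0) {
        laser <- laser_depth(offset, cam, config$depth$laser_range_cm)
        if (laser$reliable) est <- laser
      }
      if (is.null(est)) est <- ir_est
      if (is.null(est) && offset > 0) {
        est <- laser_depth(offset, cam, config$depth$laser_range_cm)
      }
      if (!is.null(est)) {
        seeds <- seed_set(dot[["x"]], dot[["y"]], sg$ttl_init)
        mask <- fuzzy_segment(img, seeds, theta = sg$theta,
                              sigma = sg$sigma)
        a_CI <- mask_area(mask)
        t <- distance_invariant_area(a_CI, est$Z_cm, cam$f_px)
        ar <- area_to_cm2(t, config$area_model$coefficients)
        report$area_cm2 <- ar$area_cm2
        report$radius_cm <- radius_from_area(ar$area_cm2)
        report$volume_cm3 <- sphere_volume(ar$area_cm2)
        report$depth <- list(Z_cm = est$Z_cm, source = est$source,
                             reliable = isTRUE(est$reliable))
        report$log$dot <- as.list(dot)
        report$log$a_CI_px <- a_CI
        report$log$t <- t
      }
    }
  }

  if (!is.null(trace)) {
    if (is.character(trace)) trace <- read_grasp_trace(trace)
    gr <- config$grading
    events <- detect_grasps(trace, on_kPa = gr$on_kPa,
                            min_duration_s = gr$min_duration_s,
                            valid_ratio = gr$valid_ratio)
    if (length(events) > 0) {
      report$pressure_kPa <- mean(vapply(events, `[[`, numeric(1),
                                         "pressure_kPa"))
      report$ripeness <- as.character(classify_ripeness(report$pressure_kPa))
      report$log$n_grasps <- length(events)
    }
  }

  feats <- c(pressure_kPa = report$pressure_kPa,
             area_cm2 = report$area_cm2,
             volume_cm3 = report$volume_cm3)
  gr <- config$grading
  usable <- intersect(names(feats),
                      intersect(names(gr$weights), names(gr$ranges)))
  if (length(usable) > 0) {
    report$quality_score <- quality_score(
      feats[usable],
      unlist(gr$weights[usable]),
      lapply(gr$ranges[usable], as.numeric)
    )
    report$alert <- quality_alert(report$quality_score,
                                  gr$alert_threshold)
  }
  structure(report, class = "fruit_report")
}

#' @export
print.fruit_report <- function(x, ...) {
  cat("<fruit_report>\n")
  if (!is.null(x$pressure_kPa)) {
    cat(sprintf("  turgor pressure: %.1f kPa (%s)\n",
                x$pressure_kPa, x$ripeness))
  }
  if (!is.null(x$area_cm2)) {
    cat(sprintf("  area %.2f cm2, radius %.2f cm, volume %.2f cm3 (Z = %.2f cm, %s)\n",
                x$area_cm2, x$radius_cm, x$volume_cm3,
                x$depth$Z_cm, x$depth$source))
  }
  if (!is.null(x$quality_score)) {
    cat(sprintf("  quality score %.3f, alert: %s\n",
                x$quality_score, x$alert))
  }
  invisible(x)
}

#' Write a fruit report as JSON
#'
#' Floats are serialized at fixed precision so identical inputs and
#' configuration give byte-identical reports.
#'
#' @param report A `fruit_report`.
#' @param path Output JSON path.
#' @export
write_fruit_report <- function(report, path) {
  stopifnot(inherits(report, "fruit_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = 6, null = "null", pretty = TRUE)
  invisible(path)
}
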