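# Synthetic scene/sensor simulator. Every generator is a pure function of
# its spec (fixed seed => identical output) and emits machine-readable
# ground truth so each downstream stage can be scored without re-deriving
# geometry.

#' Default simulator camera
#'
#' The simulator frames near-spherical fruit of radius 2-4 cm at working
#' distances of 4-7 cm. A short-focal camera (f = 100 px at 320x240) keeps
#' such fruit fully inside the frame at those distances, and a 1.0 cm
#' camera-laser baseline keeps the projected dot on the fruit even for the
#' smallest fruit at the farthest distance.
#'
#' @return A [camera_model()].
#' @export
simulator_camera <- function() {
  camera_model(width_px = 320, height_px = 240, f_px = 100,
               baseline_H_cm = 1.0)
}

#' Specification of a synthetic fruit scene
#'
#' @param radius_cm Fruit radius (sphere), cm.
#' @param Z_cm Camera-fruit distance, cm.
#' @param camera A [camera_model()]; default [simulator_camera()].
#' @param fruit_rgb,background_rgb Colours on 0-255. The default fruit is a
#'   green tomato so the saturated red laser dot is unambiguous.
#' @param laser_on Draw the projected laser dot?
#' @param noise_sd Additive Gaussian image noise, grey levels.
#' @param with_nir Also render the NIR camera's frame (shifted by the
#'   stereo relation)?
#' @param seed RNG seed making the render reproducible.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(radius_cm, Z_cm, camera = simulator_camera(),
                       fruit_rgb = c(70, 170, 80),
                       background_rgb = c(30, 30, 30),
                       laser_on = TRUE, noise_sd = 0,
                       with_nir = FALSE, seed = 1) {
  stopifnot(radius_cm > 0, Z_cm > 0, inherits(camera, "camera_model"))
  r_px <- camera$f_px * radius_cm / Z_cm
  if (2 * r_px >= min(camera$width_px, camera$height_px)) {
    stop("fruit does not fit inside the frame at this distance")
  }
  structure(list(radius_cm = radius_cm, Z_cm = Z_cm, camera = camera,
                 fruit_rgb = fruit_rgb, background_rgb = background_rgb,
                 laser_on = laser_on, noise_sd = noise_sd,
                 with_nir = with_nir, seed = seed),
            class = "scene_spec")
}

draw_disk <- function(h, w, cx, cy, r) {
  x <- matrix(rep(0:(w - 1), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1), times = w), nrow = h)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

#' Render a synthetic fruit scene with ground truth
#'
#' Rasterizes the spherical fruit as a filled disk of pixel radius
#' `f R / Z` centred on the principal point, paints the laser dot as a
#' saturated red blob at its triangulated position `cx + f H / Z` on the
#' fruit's centre row, optionally renders the NIR partner frame (the same
#' scene shifted by the stereo relation, single channel), and adds
#' Gaussian noise.
#'
#' @param spec A [scene_spec()].
#' @return List: `rgb` (HxWx3), `nir` (HxW or NULL), `truth` (list with the
#'   true mask, `a_CI_px`, dot position, `Z_cm`, `t_true`, `area_cm2`,
#'   `volume_cm3`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  cam <- spec$camera
  h <- cam$height_px; w <- cam$width_px
  r_px <- cam$f_px * spec$radius_cm / spec$Z_cm
  cx <- cam$cx; cy <- cam$cy
  mask <- draw_disk(h, w, cx, cy, r_px)

  rgb <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$background_rgb[ch], h, w)
    plane[mask] <- spec$fruit_rgb[ch]
    rgb[, , ch] <- plane
  }

  dot_xy <- NULL
  if (spec$laser_on) {
    dot_x <- cx + cam$f_px * cam$baseline_H_cm / spec$Z_cm  # sub-pixel
    dot_y <- cy
    if (!mask[round(dot_y) + 1, round(dot_x) + 1]) {
      stop("laser dot misses the fruit; enlarge the fruit or shrink Z")
    }
    dot <- draw_disk(h, w, dot_x, dot_y, 2.5)
    rgb[, , 1][dot] <- 255
    rgb[, , 2][dot] <- 60
    rgb[, , 3][dot] <- 60
    dot_xy <- c(x = dot_x, y = dot_y)
  }

  nir <- NULL
  if (spec$with_nir) {
    # NIR camera sees the planar object shifted by the stereo relation:
    # NIR(x - fH/Z) aligns with VIS(x), so the NIR frame content sits at
    # x_vis - fH/Z.
    shift <- cam$f_px * cam$baseline_H_cm / spec$Z_cm
    nir_mask <- draw_disk(h, w, cx - shift, cy, r_px)
    nir <- matrix(20, h, w)
    nir[nir_mask] <- 210  # fruit is NIR-bright
  }

  withr_seed <- spec$seed
  set.seed(withr_seed)
  if (spec$noise_sd > 0) {
    rgb <- rgb + array(stats::rnorm(length(rgb), 0, spec$noise_sd), dim(rgb))
    rgb <- pmin(pmax(rgb, 0), 255)
    if (!is.null(nir)) {
      nir <- nir + matrix(stats::rnorm(length(nir), 0, spec$noise_sd), h, w)
      nir <- pmin(pmax(nir, 0), 255)
    }
  }

  a_CI <- sum(mask)
  area_cm2 <- pi * spec$radius_cm^2
  list(
    rgb = rgb, nir = nir,
    truth = list(
      mask = mask, a_CI_px = a_CI, dot = dot_xy, Z_cm = spec$Z_cm,
      radius_cm = spec$radius_cm, r_px = r_px,
      t_true = distance_invariant_area(a_CI, spec$Z_cm, cam$f_px),
      area_cm2 = area_cm2,
      volume_cm3 = sphere_volume(area_cm2)
    )
  )
}

#' Calibrate the pixel->cm^2 area conversion for a simulator camera
#'
#' Re-enacts the bench calibration behind the stored area conversion for an
#' arbitrary camera: renders noiseless disks of known physical area, runs
#' dot detection and fuzzy segmentation on each, computes the
#' distance-invariant pixel area, and fits the polynomial mapping to cm^2
#' with [fit_area_calibration()].
#'
#' @param camera A [camera_model()]; default [simulator_camera()].
#' @param radii_cm Known disk radii rendered (default 10 circles,
#'   1.5-4.5 cm).
#' @param Z_cm Render distance (default 5.5 cm).
#' @param degree Polynomial degree passed to [fit_area_calibration()].
#' @return Coefficient vector for [area_to_cm2()].
#' @export
simulator_area_calibration <- function(camera = simulator_camera(),
                                       radii_cm = seq(1.5, 4.5,
                                                      length.out = 10),
                                       Z_cm = 5.5, degree = 2) {
  t_meas <- vapply(radii_cm, function(r) {
    sc <- render_scene(scene_spec(radius_cm = r, Z_cm = Z_cm,
                                  camera = camera, noise_sd = 0, seed = 1))
    dot <- detect_laser_dot(sc$rgb)
    mask <- fuzzy_segment(sc$rgb, seed_set(dot[["x"]], dot[["y"]], 1))
    distance_invariant_area(mask_area(mask), Z_cm, camera$f_px)
  }, numeric(1))
  fit_area_calibration(t_meas, pi * radii_cm^2, degree = degree)
}

#' Area / volume accuracy study on simulated fruit scenes
#'
#' Renders a batch of noisy fruit scenes with known geometry, runs the full
#' measurement pipeline on each (laser-dot detection, depth by laser
#' triangulation, fuzzy segmentation, distance-invariant area, spherical
#' volume), and scores the per-scene relative accuracy
#' `100 * (1 - |estimate - truth| / truth)` of the projected area and the
#' spherical volume.
#'
#' @param n_scenes Number of scenes (default 20).
#' @param radius_range,Z_range Uniform sampling ranges for fruit radius (cm)
#'   and camera distance (cm).
#' @param noise_sd Additive image noise, grey levels (default 10).
#' @param camera A [camera_model()].
#' @param coefficients Pixel->cm^2 conversion; default fitted from rendered
#'   calibration circles for `camera`.
#' @param seed Base RNG seed; scene i renders with seed `seed + i`.
#' @return data.frame with one row per scene: `radius_cm`, `Z_cm`,
#'   `area_est_cm2`, `area_true_cm2`, `area_accuracy_pct`,
#'   `volume_est_cm3`, `volume_true_cm3`, `volume_accuracy_pct`.
#' @export
area_volume_accuracy_study <- function(n_scenes = 20,
                                       radius_range = c(2, 4),
                                       Z_range = c(4, 7),
                                       noise_sd = 10,
                                       camera = simulator_camera(),
                                       coefficients =
                                         simulator_area_calibration(camera),
                                       seed = 1) {
  cfg <- default_pipeline_config()
  cfg$camera <- list(width_px = camera$width_px, height_px = camera$height_px,
                     fov_deg = NULL, f_px = camera$f_px,
                     baseline_H_cm = camera$baseline_H_cm)
  cfg$area_model$coefficients <- coefficients
  set.seed(seed)
  radii <- stats::runif(n_scenes, radius_range[1], radius_range[2])
  Zs <- stats::runif(n_scenes, Z_range[1], Z_range[2])
  rows <- lapply(seq_len(n_scenes), function(i) {
    sc <- render_scene(scene_spec(radius_cm = radii[i], Z_cm = Zs[i],
                                  camera = camera, noise_sd = noise_sd,
                                  seed = seed + i))
    rep <- run_measure(image = sc$rgb, config = cfg)
    A_true <- sc$truth$area_cm2
    V_true <- sc$truth$volume_cm3
    data.frame(
      radius_cm = radii[i], Z_cm = Zs[i],
      area_est_cm2 = rep$area_cm2, area_true_cm2 = A_true,
      area_accuracy_pct = 100 * (1 - abs(rep$area_cm2 - A_true) / A_true),
      volume_est_cm3 = rep$volume_cm3, volume_true_cm3 = V_true,
      volume_accuracy_pct = 100 * (1 - abs(rep$volume_cm3 - V_true) / V_true)
    )
  })
  do.call(rbind, rows)
}

#' Specification of a synthetic multi-finger grasp trace
#'
#' @param turgor_kPa Per-grasp turgor pressures (length = number of grasps).
#' @param contact_quality Per-finger contact fractions in `[0, 1]`; a finger
#'   whose fingertip sensor is poorly seated reads proportionally low.
#' @param pulse_s Grasp hold duration, seconds.
#' @param gap_s Gap between grasps, seconds.
#' @param noise_sd_kPa Additive Gaussian sensor noise.
#' @param sample_rate_hz Sampling rate.
#' @param seed RNG seed.
#' @return A `trace_spec` list.
#' @export
trace_spec <- function(turgor_kPa,
                       contact_quality = c(index = 1, middle = 1,
                                           ring = 1, little = 1),
                       pulse_s = 3, gap_s = 2, noise_sd_kPa = 2,
                       sample_rate_hz = 20, seed = 1) {
  stopifnot(length(turgor_kPa) >= 1, all(turgor_kPa >= 0),
            all(contact_quality >= 0), all(contact_quality <= 1),
            pulse_s > 0, gap_s > 0)
  structure(list(turgor_kPa = turgor_kPa,
                 contact_quality = contact_quality,
                 pulse_s = pulse_s, gap_s = gap_s,
                 noise_sd_kPa = noise_sd_kPa,
                 sample_rate_hz = sample_rate_hz, seed = seed),
            class = "trace_spec")
}

#' Simulate a grasp pressure trace with ground truth
#'
#' Each grasp is a smoothed rectangular pulse (raised-cosine rise and
#' release ramps of 0.4 s) of amplitude `turgor * contact_quality` per
#' finger, separated by rest gaps, plus Gaussian sensor noise, truncated
#' at zero.
#'
#' @param spec A [trace_spec()].
#' @return List: `trace` (a [grasp_trace()]), `truth` (event boundaries in
#'   samples and intended per-grasp pressures).
#' @export
simulate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  rate <- spec$sample_rate_hz
  n_p <- round(spec$pulse_s * rate)
  n_g <- round(spec$gap_s * rate)
  ramp_n <- min(round(0.4 * rate), n_p %/% 3)
  if (ramp_n * 2 > n_p) stop("pulses overlap their own ramps")
  pulse_shape <- c(
    (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2,
    rep(1, n_p - 2 * ramp_n),
    (1 + cos(pi * seq_len(ramp_n) / ramp_n)) / 2
  )
  k <- length(spec$turgor_kPa)
  n_total <- n_g + k * (n_p + n_g)
  base <- numeric(n_total)
  starts <- integer(k); ends <- integer(k)
  for (i in seq_len(k)) {
    s <- n_g + (i - 1) * (n_p + n_g) + 1
    base[s:(s + n_p - 1)] <- pulse_shape * spec$turgor_kPa[i]
    starts[i] <- s; ends[i] <- s + n_p - 1
  }
  set.seed(spec$seed)
  fingers <- names(spec$contact_quality)
  if (is.null(fingers)) {
    fingers <- paste0("finger", seq_along(spec$contact_quality))
  }
  ch <- lapply(seq_along(spec$contact_quality), function(j) {
    v <- base * spec$contact_quality[j]
    if (spec$noise_sd_kPa > 0) {
      v <- v + stats::rnorm(n_total, 0, spec$noise_sd_kPa)
    }
    pmax(0, v)
  })
  names(ch) <- fingers
  list(
    trace = grasp_trace(ch, rate),
    truth = list(starts = starts, ends = ends,
                 turgor_kPa = spec$turgor_kPa,
                 contact_quality = spec$contact_quality)
  )
}

#' Simulate noisy calibration pairs from a known transfer function
#'
#' Emulates the bench calibration procedure (impose a grid of reference
#' values, log the sensor): `x` is an even grid over the model's valid
#' range and `y = model(x) * (1 + eps)` with multiplicative Gaussian noise.
#'
#' @param true_model A [calibration_model()].
#' @param n Number of pairs (>= 2).
#' @param noise_frac Relative noise standard deviation (0 for exact pairs).
#' @param seed RNG seed.
#' @return data.frame of calibration pairs (`x_raw`, `y_ref`).
#' @export
simulate_calibration <- function(true_model, n = 13, noise_frac = 0,
                                 seed = 1) {
  stopifnot(inherits(true_model, "calibration_model"), n >= 2)
  x <- seq(true_model$valid_range[1], true_model$valid_range[2],
           length.out = n)
  y <- predict_calibration(true_model, x)
  set.seed(seed)
  if (noise_frac > 0) y <- y * (1 + stats::rnorm(n, 0, noise_frac))
  data.frame(x_raw = x, y_ref = y)
}
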