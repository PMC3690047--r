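#' Pin-hole camera model
#'
#' Holds the intrinsic and layout parameters the geometric pipeline needs:
#' image resolution, focal length in pixels (given directly or derived from
#' the horizontal field of view), and the baseline `H` between the reference
#' camera and its partner sensor (second camera or laser pointer), in cm.
#'
#' @param width_px,height_px Image resolution in pixels.
#' @param fov_deg Horizontal field of view in degrees; used to derive
#'   `f_px` when the focal length is not given directly.
#' @param f_px Focal length in pixels; overrides `fov_deg` when supplied.
#' @param baseline_H_cm Baseline between the camera and the laser or the
#'   second camera, in cm.
#' @return An object of class `camera_model`. The principal point is the
#'   image centre; pixel coordinates are 0-based, origin top-left,
#'   x rightward.
#' @export
camera_model <- function(width_px = 640, height_px = 480, fov_deg = 48,
                         f_px = NULL, baseline_H_cm = 2.5) {
  stopifnot(width_px > 0, height_px > 0, baseline_H_cm >= 0)
  if (is.null(f_px)) {
    f_px <- focal_from_fov(width_px, fov_deg)
  } else {
    stopifnot(f_px > 0)
    fov_deg <- 2 * atan((width_px / 2) / f_px) * 180 / pi
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         fov_deg = fov_deg, f_px = f_px, baseline_H_cm = baseline_H_cm,
         cx = width_px / 2, cy = height_px / 2),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %dx%d px, f = %.1f px (FOV %.1f deg), H = %g cm\n",
              x$width_px, x$height_px, x$f_px, x$fov_deg, x$baseline_H_cm))
  invisible(x)
}

#' Focal length in pixels from the horizontal field of view
#'
#' @param width_px Image width in pixels.
#' @param fov_deg Horizontal FOV in degrees, in (0, 180).
#' @return Focal length in pixels: `(width_px/2) / tan(fov_deg/2)`.
#' @export
focal_from_fov <- function(width_px, fov_deg) {
  stopifnot(width_px > 0)
  if (any(fov_deg <= 0 | fov_deg >= 180)) stop("fov_deg must be in (0, 180)")
  (width_px / 2) / tan(fov_deg * pi / 360)
}

#' Depth from stereo disparity
#'
#' Standard rectified-stereo relation `Z = f H / (xL - xR)`: the same world
#' point appears at column `xL` in the left image and `xR` in the right, and
#' the horizontal offset (disparity) is inversely proportional to depth.
#'
#' @param xL,xR Corresponding column coordinates in the left/right image.
#' @param cam A [camera_model()] supplying `f_px` and `baseline_H_cm`.
#' @return Depth Z in cm.
#' @export
stereo_depth <- function(xL, xR, cam) {
  stopifnot(inherits(cam, "camera_model"))
  d <- xL - xR
  if (any(d == 0)) stop("zero disparity: object at infinity")
  cam$f_px * cam$baseline_H_cm / d
}

#' Disparity expected at a given depth
#'
#' Inverse of [stereo_depth()]: `xL = xR + f H / Z`.
#'
#' @param Z Depth in cm (> 0).
#' @param cam A [camera_model()].
#' @return Pixel offset `f H / Z`.
#' @export
disparity_for_depth <- function(Z, cam) {
  stopifnot(inherits(cam, "camera_model"), all(Z > 0))
  cam$f_px * cam$baseline_H_cm / Z
}

#' Depth from the projected laser dot
#'
#' The laser beam runs parallel to the optical axis at baseline `H`, so the
#' bright dot it projects on the object appears offset from the principal
#' point by `f H / Z` pixels along the baseline axis; inverting gives depth
#' by triangulation. The short glove baseline makes this accurate only over
#' a small working range, outside which the estimate is flagged unreliable.
#'
#' @param dot_offset_px Offset of the detected dot from the principal point
#'   along the baseline axis, in pixels (> 0).
#' @param cam A [camera_model()].
#' @param reliable_range_cm Depth range over which laser triangulation is
#'   trusted; default 3-7.3 cm.
#' @return A `depth_estimate` list: `Z_cm`, `source = "laser"`, `reliable`.
#' @export
laser_depth <- function(dot_offset_px, cam, reliable_range_cm = c(3, 7.3)) {
  stopifnot(inherits(cam, "camera_model"))
  if (any(dot_offset_px <= 0)) stop("laser dot offset must be positive")
  Z <- cam$f_px * cam$baseline_H_cm / dot_offset_px
  depth_estimate(Z, "laser",
                 Z >= reliable_range_cm[1] & Z <= reliable_range_cm[2])
}

#' @rdname laser_depth
#' @param Z_cm Depth in cm.
#' @param source One of `"laser"`, `"ir_sensor"`, `"stereo"`.
#' @param reliable Logical reliability flag.
#' @export
depth_estimate <- function(Z_cm, source, reliable = TRUE) {
  stopifnot(all(Z_cm > 0),
            source %in% c("laser", "ir_sensor", "stereo"))
  structure(list(Z_cm = Z_cm, source = source, reliable = reliable),
            class = "depth_estimate")
}

#' Largest fully visible object diameter at a given distance
#'
#' @param Z Distance camera to object, cm.
#' @param cam A [camera_model()].
#' @return Diameter in cm: `2 Z tan(fov/2)`. At Z = 31 cm a 48-degree FOV
#'   camera frames about a 28 cm object.
#' @export
max_visible_diameter <- function(Z, cam) {
  stopifnot(inherits(cam, "camera_model"), all(Z >= 0))
  2 * Z * tan(cam$fov_deg * pi / 360)
}
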