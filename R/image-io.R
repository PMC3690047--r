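# Images are plain numeric arrays on a 0-255 scale: height x width x 3 for
# RGB, height x width for single-channel (NIR, masks use logical matrices).
# Pixel coordinates are 0-based with origin top-left, x rightward (column),
# y downward (row).

#' Read / write images as PNG
#'
#' Thin wrappers over the png package keeping the package-wide convention
#' of 0-255 numeric arrays.
#'
#' @param path PNG file path.
#' @return `read_image`: numeric array (HxWx3) or matrix (HxW) on 0-255.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) == 3) {
    img <- img[, , 1]
  }
  img * 255
}

#' @rdname read_image
#' @param img Numeric array/matrix on the 0-255 scale.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Per-pixel intensity of an RGB image
#'
#' @param img HxWx3 array (0-255).
#' @return HxW matrix of per-channel means.
#' @export
rgb_intensity <- function(img) {
  if (length(dim(img)) == 2) return(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

#' Fuse a visible RGB image with a NIR image into a 4-channel image
#'
#' The visible and NIR cameras are horizontally aligned at baseline `H`;
#' assuming the object of interest is planar at known depth `Z`, every NIR
#' pixel corresponding to visible pixel `(x, y)` sits at `(x - f H / Z, y)`.
#' The fused image keeps R, G, B from the visible camera unchanged and adds
#' an I channel resampled from the NIR frame under that shift; source
#' columns falling outside the NIR frame yield I = 0 and are flagged.
#'
#' @param vis HxWx3 visible image (0-255).
#' @param nir HxW single-channel NIR image (0-255).
#' @param Z Planar object depth in cm.
#' @param cam A [camera_model()] supplying `f_px` and `baseline_H_cm`.
#' @return List: `image` (HxWx4 array, channels R,G,B,I), `oob` (logical
#'   HxW matrix of out-of-bounds NIR lookups), `shift_px`.
#' @export
merge_nir <- function(vis, nir, Z, cam) {
  stopifnot(length(dim(vis)) == 3, dim(vis)[3] == 3, is.matrix(nir))
  if (!all(dim(vis)[1:2] == dim(nir))) {
    stop("visible and NIR images must have identical dimensions")
  }
  stopifnot(Z > 0, inherits(cam, "camera_model"))
  h <- dim(vis)[1]; w <- dim(vis)[2]
  shift <- cam$f_px * cam$baseline_H_cm / Z
  # source column (0-based) for each destination column, linear interpolation
  dst <- seq_len(w) - 1
  src <- dst - shift
  lo <- floor(src); frac <- src - lo
  oob_col <- src < 0 | src > (w - 1)
  lo_c <- pmin(w - 1, pmax(0, lo))
  hi_c <- pmin(w - 1, lo_c + 1)
  I <- nir[, lo_c + 1, drop = FALSE] * rep(1 - frac, each = h) +
       nir[, hi_c + 1, drop = FALSE] * rep(frac, each = h)
  I[, oob_col] <- 0
  fused <- array(0, dim = c(h, w, 4))
  fused[, , 1:3] <- vis
  fused[, , 4] <- I
  oob <- matrix(rep(oob_col, each = h), nrow = h)
  list(image = fused, oob = oob, shift_px = shift)
}
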