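#' Detect the projected laser dot
#'
#' The glove's laser projects a very bright red filled circle on the pointed
#' object. Detection scores every pixel by its redness `s = R - max(G, B)`
#' and returns the brightest-red pixel, provided it is red enough
#' (`s >= score_threshold`) and bright enough (`R >= min_brightness`).
#' Ties are broken by smallest `(y, x)`.
#'
#' @param rgb HxWx3 image on 0-255.
#' @param score_threshold Minimum redness score (default 60).
#' @param min_brightness Minimum red-channel value (default 200).
#' @return Named numeric `c(x, y)` (0-based pixel coordinates), or `NULL`
#'   when no pixel qualifies.
#' @export
detect_laser_dot <- function(rgb, score_threshold = 60, min_brightness = 200) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("detect_laser_dot expects a 3-channel image")
  }
  R <- rgb[, , 1]
  s <- R - pmax(rgb[, , 2], rgb[, , 3])
  ok <- s >= score_threshold & R >= min_brightness
  if (!any(ok)) return(NULL)
  s[!ok] <- -Inf
  best <- max(s)
  idx <- which(s == best)          # column-major: increasing x, then y
  rows <- (idx - 1) %% nrow(s)     # 0-based y
  cols <- (idx - 1) %/% nrow(s)    # 0-based x
  pick <- order(rows, cols)[1]
  c(x = cols[pick], y = rows[pick])
}

#' Refine a detected laser dot to sub-pixel precision
#'
#' The laser projects a filled blob several pixels wide; the argmax pixel
#' returned by [detect_laser_dot()] quantizes its position to a pixel,
#' which propagates into the triangulated depth. Refinement takes the
#' redness-weighted centroid of qualifying pixels in a small neighbourhood
#' of the detection.
#'
#' @param rgb HxWx3 image on 0-255.
#' @param dot `c(x, y)` from [detect_laser_dot()].
#' @param radius Neighbourhood half-width in pixels (default 4).
#' @param score_threshold Minimum redness score for a pixel to contribute.
#' @return Named numeric `c(x, y)`, sub-pixel.
#' @export
refine_dot <- function(rgb, dot, radius = 4, score_threshold = 60) {
  s <- rgb[, , 1] - pmax(rgb[, , 2], rgb[, , 3])
  h <- nrow(s); w <- ncol(s)
  rows <- max(1, round(dot[["y"]]) + 1 - radius):min(h, round(dot[["y"]]) + 1 + radius)
  cols <- max(1, round(dot[["x"]]) + 1 - radius):min(w, round(dot[["x"]]) + 1 + radius)
  sub <- s[rows, cols, drop = FALSE]
  wgt <- pmax(0, sub - score_threshold)
  if (sum(wgt) == 0) return(dot)
  xs <- matrix(rep(cols - 1, each = length(rows)), nrow = length(rows))
  ys <- matrix(rep(rows - 1, times = length(cols)), nrow = length(rows))
  c(x = sum(wgt * xs) / sum(wgt), y = sum(wgt * ys) / sum(wgt))
}

#' Seed sets for interactive segmentation
#'
#' Each detected laser dot becomes a seed pixel from which segmentation
#' grows. Seeds carry a time-to-live (TTL) in frames so that stale or
#' spurious seeds left behind by hand motion expire instead of degrading
#' the segmentation.
#'
#' @param x,y 0-based pixel coordinates.
#' @param ttl Remaining frames for each seed (integer >= 0).
#' @return A `seed_set`: data.frame with columns `x`, `y`, `ttl`.
#' @export
seed_set <- function(x = numeric(), y = numeric(), ttl = integer()) {
  if (length(ttl) == 1 && length(x) > 1) ttl <- rep(ttl, length(x))
  stopifnot(length(x) == length(y), length(y) == length(ttl),
            all(ttl >= 0))
  structure(data.frame(x = as.numeric(x), y = as.numeric(y),
                       ttl = as.integer(ttl)),
            class = c("seed_set", "data.frame"))
}

clip_seeds <- function(seeds, h, w) {
  keep <- seeds$x >= 0 & seeds$x <= (w - 1) &
          seeds$y >= 0 & seeds$y <= (h - 1)
  seeds[keep, , drop = FALSE]
}

#' Fuzzy-connectedness segmentation from laser seeds
#'
#' Seeded region growing under a fuzzy affinity: a pixel `q` belongs to the
#' object if some 4-connected path from a seed to `q` has min-link affinity
#' at least `theta`, with link affinity
#' `mu(p, q) = exp(-(I(p) - I(q))^2 / (2 sigma^2))` on per-channel mean
#' intensity. Because the path criterion is a max-min, this is equivalent
#' to a flood fill over links whose intensity step is at most
#' `sigma * sqrt(-2 log(theta))`, which is how it is computed.
#'
#' @param img RGB array or intensity matrix (0-255).
#' @param seeds A [seed_set()] with at least one live seed.
#' @param theta Affinity threshold in (0, 1]; larger is stricter.
#' @param sigma Affinity bandwidth in grey levels (default 25).
#' @return A `seg_mask`: logical HxW matrix, TRUE for object pixels.
#' @export
fuzzy_segment <- function(img, seeds, theta = 0.7, sigma = 25) {
  stopifnot(inherits(seeds, "seed_set"), theta > 0, theta <= 1, sigma > 0)
  if (nrow(seeds) == 0) stop("fuzzy_segment requires at least one seed")
  I <- rgb_intensity(img)
  h <- nrow(I); w <- ncol(I)
  seeds <- clip_seeds(seeds, h, w)
  if (nrow(seeds) == 0) stop("all seeds fall outside the image")
  # max-min path criterion <=> flood fill over admissible links
  dmax <- if (theta >= 1) 0 else sigma * sqrt(-2 * log(theta))

  visited <- logical(h * w)
  idx0 <- unique(round(seeds$y) + 1 + round(seeds$x) * h)
  visited[idx0] <- TRUE
  frontier <- idx0
  Iv <- as.vector(I)
  while (length(frontier) > 0) {
    rows <- (frontier - 1) %% h
    cand <- c(frontier[rows > 0] - 1L,
              frontier[rows < (h - 1)] + 1L,
              frontier[frontier > h] - h,
              frontier[frontier <= h * (w - 1)] + h)
    from <- c(frontier[rows > 0],
              frontier[rows < (h - 1)],
              frontier[frontier > h],
              frontier[frontier <= h * (w - 1)])
    ok <- !visited[cand] & abs(Iv[cand] - Iv[from]) <= dmax
    nxt <- unique(cand[ok])
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  structure(matrix(visited, nrow = h, ncol = w), class = "seg_mask")
}

#' Pixel area of a segmentation mask
#'
#' The number of segmented pixels is the object's image area `a_CI`.
#'
#' @param mask A logical mask (e.g. from [fuzzy_segment()]).
#' @return Integer count of set pixels.
#' @export
mask_area <- function(mask) sum(mask)

#' Moving-fovea window
#'
#' Restricts expensive vision computation (disparity) to a window centred on
#' the object of interest — by default the last laser-dot position — and
#' clipped to the image bounds.
#'
#' @param cx,cy Window centre, 0-based pixel coordinates.
#' @param half_width,half_height Half extents in pixels (default 64).
#' @param width_px,height_px Image dimensions used for clipping.
#' @return A `fovea_window` list with 0-based inclusive bounds
#'   `x0, x1, y0, y1`.
#' @export
fovea_window <- function(cx, cy, half_width = 64, half_height = 64,
                         width_px, height_px) {
  x0 <- max(0, round(cx) - half_width)
  x1 <- min(width_px - 1, round(cx) + half_width)
  y0 <- max(0, round(cy) - half_height)
  y1 <- min(height_px - 1, round(cy) + half_height)
  if (x0 > x1 || y0 > y1) stop("fovea window falls outside the image")
  structure(list(x0 = x0, x1 = x1, y0 = y0, y1 = y1),
            class = "fovea_window")
}

# summed-area box filter, box = (2r+1)^2, border handled by clamping
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  cs <- apply(m, 2, cumsum)
  up <- rbind(matrix(0, 1, w), cs)
  col_sum <- up[pmin(h, seq_len(h) + r) + 1, , drop = FALSE] -
             up[pmax(0, seq_len(h) - r - 1) + 1, , drop = FALSE]
  cs2 <- t(apply(col_sum, 1, cumsum))
  left <- cbind(matrix(0, h, 1), cs2)
  left[, pmin(w, seq_len(w) + r) + 1, drop = FALSE] -
    left[, pmax(0, seq_len(w) - r - 1) + 1, drop = FALSE]
}

#' Block-matching disparity inside a fovea window
#'
#' Integer-disparity stereo matching on a rectified, horizontally aligned
#' pair, computed only inside the fovea window: for each candidate disparity
#' the sum of absolute differences over a square block is evaluated, and
#' each window pixel takes the disparity minimising its block SAD.
#'
#' @param left,right Intensity matrices (or RGB arrays) of equal size;
#'   the left image is the reference.
#' @param window A [fovea_window()].
#' @param max_disp Largest disparity searched (candidates `0:max_disp`).
#' @param block_size Odd SAD block edge (default 7).
#' @return List: `disparity` (integer matrix over the window, rows = window
#'   rows), `window`.
#' @export
fovea_disparity <- function(left, right, window, max_disp, block_size = 7) {
  L <- rgb_intensity(left); R <- rgb_intensity(right)
  stopifnot(all(dim(L) == dim(R)), inherits(window, "fovea_window"),
            block_size %% 2 == 1)
  h <- nrow(L); w <- ncol(L)
  r <- (block_size - 1) %/% 2
  rows <- (window$y0 + 1):(window$y1 + 1)
  cols <- (window$x0 + 1):(window$x1 + 1)
  best_cost <- matrix(Inf, length(rows), length(cols))
  best_d <- matrix(0L, length(rows), length(cols))
  for (d in 0:max_disp) {
    # right image sampled at x - d; clamp the first d columns
    src <- pmax(1, seq_len(w) - d)
    sad <- box_sum(abs(L - R[, src, drop = FALSE]), r)
    cost <- sad[rows, cols, drop = FALSE]
    upd <- cost < best_cost
    best_cost[upd] <- cost[upd]
    best_d[upd] <- d
  }
  list(disparity = best_d, window = window)
}
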