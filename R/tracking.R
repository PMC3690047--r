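# Pyramidal Lucas-Kanade point tracking used to carry laser seeds from
# frame to frame while the hand moves.

pyr_down <- function(I) {
  h <- 2 * (nrow(I) %/% 2); w <- 2 * (ncol(I) %/% 2)
  I <- I[seq_len(h), seq_len(w), drop = FALSE]
  (I[seq(1, h, 2), seq(1, w, 2)] + I[seq(2, h, 2), seq(1, w, 2)] +
   I[seq(1, h, 2), seq(2, w, 2)] + I[seq(2, h, 2), seq(2, w, 2)]) / 4
}

# bilinear sampling at 0-based (x, y); coordinates clamped to the border
bilinear <- function(I, x, y) {
  h <- nrow(I); w <- ncol(I)
  x <- pmin(w - 1, pmax(0, x)); y <- pmin(h - 1, pmax(0, y))
  x0 <- pmin(w - 2, floor(x)); y0 <- pmin(h - 2, floor(y))
  fx <- x - x0; fy <- y - y0
  i00 <- I[cbind(y0 + 1, x0 + 1)]
  i01 <- I[cbind(y0 + 1, x0 + 2)]
  i10 <- I[cbind(y0 + 2, x0 + 1)]
  i11 <- I[cbind(y0 + 2, x0 + 2)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

lk_point <- function(prev, cur, x, y, guess, win = 7, iters = 15) {
  offs <- expand.grid(dx = -win:win, dy = -win:win)
  px <- x + offs$dx; py <- y + offs$dy
  I1 <- bilinear(prev, px, py)
  Ix <- (bilinear(prev, px + 1, py) - bilinear(prev, px - 1, py)) / 2
  Iy <- (bilinear(prev, px, py + 1) - bilinear(prev, px, py - 1)) / 2
  G <- matrix(c(sum(Ix^2), sum(Ix * Iy), sum(Ix * Iy), sum(Iy^2)), 2)
  if (abs(det(G)) < 1e-8) return(guess)  # textureless window: keep guess
  g <- guess
  for (i in seq_len(iters)) {
    I2 <- bilinear(cur, px + g[1], py + g[2])
    e <- I1 - I2
    d <- solve(G, c(sum(Ix * e), sum(Iy * e)))
    g <- g + d
    if (sum(d^2) < 1e-4) break
  }
  g
}

#' Track points between two frames with pyramidal Lucas-Kanade flow
#'
#' Window-based least-squares optical flow, run coarse-to-fine over an
#' image pyramid so that displacements of several pixels converge.
#'
#' @param prev,cur Consecutive intensity matrices or RGB arrays of equal
#'   dimensions.
#' @param pts data.frame with 0-based columns `x`, `y`.
#' @param win Half-width of the tracking window (default 7).
#' @param levels Pyramid levels (default 3).
#' @return data.frame with tracked `x`, `y`.
#' @export
lk_track <- function(prev, cur, pts, win = 7, levels = 3) {
  P <- rgb_intensity(prev); C <- rgb_intensity(cur)
  if (!all(dim(P) == dim(C))) stop("frames must have identical dimensions")
  pyrP <- list(P); pyrC <- list(C)
  for (l in seq_len(levels - 1)) {
    if (min(dim(pyrP[[l]])) < 2 * (2 * win + 1)) { levels <- l; break }
    pyrP[[l + 1]] <- pyr_down(pyrP[[l]])
    pyrC[[l + 1]] <- pyr_down(pyrC[[l]])
  }
  levels <- min(levels, length(pyrP))
  out <- pts
  for (i in seq_len(nrow(pts))) {
    g <- c(0, 0)
    for (l in levels:1) {
      s <- 2^(l - 1)
      g <- lk_point(pyrP[[l]], pyrC[[l]], pts$x[i] / s, pts$y[i] / s,
                    g, win = win)
      if (l > 1) g <- g * 2
    }
    out$x[i] <- pts$x[i] + g[1]
    out$y[i] <- pts$y[i] + g[2]
  }
  out
}

#' Advance the laser seed set by one frame
#'
#' Tracks every live seed from the previous frame into the current one with
#' [lk_track()], decrements each seed's time-to-live, drops seeds that
#' expired or left the image, and appends the newly detected laser dot (if
#' any) with a fresh TTL.
#'
#' @param seeds A [seed_set()].
#' @param prev,cur Consecutive frames (equal dimensions).
#' @param new_dot Optional `c(x, y)` of the laser dot detected in `cur`.
#' @param ttl_init TTL granted to a new seed, in frames (default 30).
#' @return The updated `seed_set`.
#' @export
advance_seeds <- function(seeds, prev, cur, new_dot = NULL, ttl_init = 30) {
  stopifnot(inherits(seeds, "seed_set"))
  P <- rgb_intensity(prev); C <- rgb_intensity(cur)
  if (!all(dim(P) == dim(C))) stop("frames must have identical dimensions")
  h <- nrow(C); w <- ncol(C)
  if (nrow(seeds) > 0) {
    moved <- lk_track(P, C, seeds[, c("x", "y")])
    seeds$x <- moved$x
    seeds$y <- moved$y
    seeds$ttl <- seeds$ttl - 1L
    seeds <- seeds[seeds$ttl > 0, , drop = FALSE]
    seeds <- clip_seeds(seeds, h, w)
  }
  if (!is.null(new_dot)) {
    seeds <- rbind(seeds,
                   data.frame(x = new_dot[[1]], y = new_dot[[2]],
                              ttl = as.integer(ttl_init)))
  }
  structure(seeds, class = c("seed_set", "data.frame"))
}
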