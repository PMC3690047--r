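# Shared fixtures and independent oracles, all built in code.

iou <- function(a, b) sum(a & b) / sum(a | b)

# Independent flood-fill oracle: connected region (4-connectivity) of pixels
# whose intensity step from an accepted neighbour is at most `tol`, grown by
# whole-image dilation — a different algorithm from the package's
# frontier-queue fuzzy segmentation.
flood_fill_oracle <- function(I, seed_x, seed_y, tol = 0.5) {
  h <- nrow(I); w <- ncol(I)
  mask <- matrix(FALSE, h, w)
  mask[seed_y + 1, seed_x + 1] <- TRUE
  repeat {
    up    <- rbind(mask[-1, , drop = FALSE], FALSE)
    down  <- rbind(FALSE, mask[-h, , drop = FALSE])
    left  <- cbind(mask[, -1, drop = FALSE], FALSE)
    right <- cbind(FALSE, mask[, -w, drop = FALSE])
    shift_ok <- function(nb, src_I) nb & abs(I - src_I) <= tol
    Iu <- rbind(I[-1, , drop = FALSE], NA)
    Id <- rbind(NA, I[-h, , drop = FALSE])
    Il <- cbind(I[, -1, drop = FALSE], NA)
    Ir <- cbind(NA, I[, -w, drop = FALSE])
    grow <- (up & abs(I - Iu) <= tol) | (down & abs(I - Id) <= tol) |
            (left & abs(I - Il) <= tol) | (right & abs(I - Ir) <= tol)
    grow[is.na(grow)] <- FALSE
    new_mask <- mask | grow
    if (identical(new_mask, mask)) break
    mask <- new_mask
  }
  mask
}

# Analytic smooth texture so a shifted copy can be generated exactly.
textured_frame <- function(h, w, dx = 0, dy = 0) {
  x <- matrix(rep(0:(w - 1), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1), times = w), nrow = h)
  128 + 50 * sin((x - dx) / 6) * cos((y - dy) / 8) +
    30 * sin((x - dx) / 13 + (y - dy) / 11)
}

# Uniform disk on uniform background (noiseless unless sd > 0).
disk_image <- function(h = 80, w = 100, cx = 50, cy = 40, r = 25,
                       fg = 200, bg = 30, sd = 0, seed = 1) {
  x <- matrix(rep(0:(w - 1), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1), times = w), nrow = h)
  inside <- (x - cx)^2 + (y - cy)^2 <= r^2
  I <- matrix(bg, h, w)
  I[inside] <- fg
  if (sd > 0) {
    set.seed(seed)
    I <- I + matrix(rnorm(h * w, 0, sd), h, w)
  }
  list(img = I, mask = inside)
}
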