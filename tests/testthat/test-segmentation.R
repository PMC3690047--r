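make_rgb <- function(h, w, val = 0) array(val, dim = c(h, w, 3))

test_that("the brightest red pixel is found, with deterministic ties", {
  img <- make_rgb(100, 150, 30)
  img[81, 121, ] <- c(255, 40, 40)  # dot at (x=120, y=80)
  expect_equal(detect_laser_dot(img), c(x = 120, y = 80))

  expect_null(detect_laser_dot(make_rgb(50, 50, 0)))

  two <- make_rgb(60, 60, 0)
  two[11, 11, ] <- c(255, 0, 0)
  two[11, 41, ] <- c(255, 0, 0)
  expect_equal(detect_laser_dot(two), c(x = 10, y = 10))

  # red enough but too dim, or bright but not red: rejected
  dim_dot <- make_rgb(20, 20, 0); dim_dot[5, 5, ] <- c(150, 10, 10)
  expect_null(detect_laser_dot(dim_dot))
  white <- make_rgb(20, 20, 0); white[5, 5, ] <- c(255, 255, 255)
  expect_null(detect_laser_dot(white))
  expect_error(detect_laser_dot(matrix(0, 5, 5)), "3-channel")
})

test_that("fuzzy segmentation extracts a uniform disk exactly", {
  d <- disk_image()
  mask <- fuzzy_segment(d$img, seed_set(50, 40, 10))
  oracle <- flood_fill_oracle(d$img, 50, 40)
  expect_identical(unclass(mask), oracle)
  expect_identical(unclass(mask), d$mask)
  expect_equal(mask_area(mask), sum(d$mask))
})

test_that("theta = 1 on a noisy image keeps only the seed pixels", {
  d <- disk_image(sd = 5, seed = 9)
  seeds <- seed_set(c(50, 20), c(40, 10), c(5, 5))
  mask <- fuzzy_segment(d$img, seeds, theta = 1)
  expect_equal(mask_area(mask), 2)
  expect_true(mask[41, 51] && mask[11, 21])
})

test_that("two seeds in disjoint disks segment the union of both", {
  h <- 60; w <- 120
  x <- matrix(rep(0:(w - 1), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1), times = w), nrow = h)
  d1 <- (x - 30)^2 + (y - 30)^2 <= 15^2
  d2 <- (x - 90)^2 + (y - 30)^2 <= 12^2
  I <- matrix(30, h, w); I[d1] <- 200; I[d2] <- 200
  mask <- fuzzy_segment(I, seed_set(c(30, 90), c(30, 30), c(5, 5)))
  oracle <- flood_fill_oracle(I, 30, 30) | flood_fill_oracle(I, 90, 30)
  expect_identical(unclass(mask), oracle)
  expect_identical(unclass(mask), d1 | d2)
})

test_that("segmentation is monotone in theta and contains all live seeds", {
  d <- disk_image(sd = 8, seed = 3)
  seeds <- seed_set(c(50, 45), c(40, 35), c(5, 5))
  thetas <- c(0.3, 0.5, 0.7, 0.9)
  masks <- lapply(thetas, function(th) fuzzy_segment(d$img, seeds, theta = th))
  for (k in seq_along(thetas)[-1]) {
    expect_true(all(masks[[k]] <= masks[[k - 1]]))  # stricter => subset
  }
  for (m in masks) {
    expect_true(all(m[cbind(seeds$y + 1, seeds$x + 1)]))
  }
})

test_that("noisy simulator disks segment with IoU >= 0.9", {
  for (seed in 1:5) {
    sc <- render_scene(scene_spec(radius_cm = 3, Z_cm = 5, noise_sd = 10,
                                  seed = seed))
    dot <- detect_laser_dot(sc$rgb)
    mask <- fuzzy_segment(sc$rgb, seed_set(dot[["x"]], dot[["y"]], 30))
    expect_gte(iou(mask, sc$truth$mask), 0.9)
  }
})

test_that("segmentation requires at least one in-image seed", {
  d <- disk_image()
  expect_error(fuzzy_segment(d$img, seed_set()), "seed")
  expect_error(fuzzy_segment(d$img, seed_set(500, 500, 5)), "outside")
})

test_that("mask area counts set pixels", {
  expect_equal(mask_area(matrix(FALSE, 10, 10)), 0)
  expect_equal(mask_area(matrix(TRUE, 10, 10)), 100)
  d <- disk_image(r = 50, h = 120, w = 120, cx = 60, cy = 60)
  expect_equal(sum(d$mask), pi * 50^2, tolerance = 0.02)
})

test_that("dot refinement recovers sub-pixel laser positions", {
  sc <- render_scene(scene_spec(radius_cm = 3, Z_cm = 5.3, noise_sd = 10,
                                seed = 21))
  dot <- detect_laser_dot(sc$rgb)
  fine <- refine_dot(sc$rgb, dot)
  expect_lt(abs(fine[["x"]] - sc$truth$dot[["x"]]), 0.5)
  expect_lt(abs(fine[["y"]] - sc$truth$dot[["y"]]), 0.5)
})

test_that("fovea window clips to the image and block matching recovers shift", {
  w <- fovea_window(10, 10, 64, 64, width_px = 100, height_px = 80)
  expect_equal(c(w$x0, w$y0), c(0, 0))
  expect_equal(c(w$x1, w$y1), c(74, 74))
  expect_error(fovea_window(-200, 10, 10, 10, 100, 80), "outside")

  left <- textured_frame(60, 90)
  win <- fovea_window(45, 30, 15, 15, width_px = 90, height_px = 60)
  same <- fovea_disparity(left, left, win, max_disp = 6)
  expect_true(all(same$disparity == 0))
  expect_equal(dim(same$disparity), c(31, 31))

  right <- textured_frame(60, 90, dx = -4)  # content 4 px left of reference
  shifted <- fovea_disparity(left, right, win, max_disp = 8)
  expect_equal(median(shifted$disparity), 4)
  expect_gte(mean(shifted$disparity == 4), 0.9)
})
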