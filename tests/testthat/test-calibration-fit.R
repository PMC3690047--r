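test_that("linear fit recovers exact coefficients and r^2 = 1", {
  pairs <- data.frame(x_raw = 0:6, y_ref = 2 * (0:6) + 1)
  m <- fit_model(pairs, "linear")
  expect_equal(m$coefficients, c(2, 1), tolerance = 1e-10)
  expect_equal(m$r_squared, 1)
  expect_equal(m$valid_range, c(0, 6))
})

test_that("fits round-trip noiseless samples of every stored form", {
  forms <- list(
    linear = calibration_model("linear", c(0.83, -0.02),
                               valid_range = c(0, 6)),
    poly2 = calibration_model("poly2", c(0.0802, -0.77, 2.606),
                              valid_range = c(0.5, 5)),
    power = calibration_model("power", c(3.29, -2.061),
                              valid_range = c(0.5, 4))
  )
  for (form in names(forms)) {
    pairs <- simulate_calibration(forms[[form]], n = 15, noise_frac = 0)
    refit <- fit_model(pairs, form)
    expect_equal(refit$coefficients, forms[[form]]$coefficients,
                 tolerance = 1e-6)
    expect_gt(refit$r_squared, 1 - 1e-9)
  }
})

test_that("power fit recovers parameters within 5% from 30 noisy pairs", {
  truth <- calibration_model("power", c(3.29, -2.061),
                             valid_range = c(0.5, 4))
  pairs <- simulate_calibration(truth, n = 30, noise_frac = 0.05, seed = 11)
  m <- fit_model(pairs, "power")
  expect_equal(m$coefficients[1], 3.29, tolerance = 0.05)
  expect_equal(m$coefficients[2], -2.061, tolerance = 0.05)
})

test_that("power form outfits the polynomial on FSR-style data", {
  # FSR physics: inverse power law response plus multiplicative noise
  truth <- calibration_model("power", c(3.29, -2.061),
                             valid_range = c(0.5, 4))
  pairs <- simulate_calibration(truth, n = 30, noise_frac = 0.05, seed = 5)
  m_pow <- fit_model(pairs, "power")
  m_poly <- fit_model(pairs, "poly2")
  expect_gte(m_pow$r_squared, m_poly$r_squared)
})

test_that("fit errors on degenerate or insufficient input", {
  expect_error(fit_model(data.frame(x_raw = 1, y_ref = 1), "linear"),
               "too few")
  expect_error(fit_model(data.frame(x_raw = c(1, 1, 1), y_ref = 1:3),
                         "poly2"), "degenerate")
  expect_error(fit_model(data.frame(x_raw = c(-1, 2, 3), y_ref = 1:3),
                         "power"), "positive")
})

test_that("bend spline interpolates its knots exactly", {
  m <- fit_bend_spline(bend_reference_pairs())
  expect_equal(bend_to_diameter(m, 887)$diameter_mm, 25)
  expect_equal(bend_to_diameter(m, 809)$diameter_mm, 150)
  expect_equal(bend_to_diameter(m, 859)$diameter_mm, 50)
  # strictly decreasing between knots (dense grid scan)
  grid <- seq(809, 887, by = 0.25)
  expect_true(all(diff(predict_calibration(m, grid)) < 0))
  expect_error(fit_bend_spline(data.frame(x_raw = c(1, 3, 2),
                                          y_ref = c(1, 2, 3))),
               "monotone")
})

test_that("bend readings outside the calibrated span are clamped and flagged", {
  m <- fit_bend_spline(bend_reference_pairs())
  expect_warning(res <- bend_to_diameter(m, 900), "clamped")
  expect_true(res$extrapolated)
  expect_equal(res$diameter_mm, 25)  # clamped to the 887 knot
  res_in <- bend_to_diameter(m, 860)
  expect_false(res_in$extrapolated)
})

test_that("calibration models survive a JSON round trip", {
  tmp <- withr::local_tempfile(fileext = ".json")
  m <- fit_model(data.frame(x_raw = c(0.5, 1, 2, 4),
                            y_ref = fsr_pressure(c(0.5, 1, 2, 4))), "power",
                 input_units = "V", output_units = "kgf/cm2")
  write_calibration_model(m, tmp)
  m2 <- read_calibration_model(tmp)
  expect_equal(m2$form, "power")
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$valid_range, m$valid_range)
  x <- seq(0.5, 4, length.out = 7)
  expect_equal(predict_calibration(m2, x), predict_calibration(m, x))

  s <- fit_bend_spline(bend_reference_pairs())
  write_calibration_model(s, tmp)
  s2 <- read_calibration_model(tmp)
  expect_equal(predict_calibration(s2, 820:880), predict_calibration(s, 820:880))
})

test_that("calibration pairs load from CSV with required header", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x_raw = 1:4, y_ref = (1:4)^2), tmp, row.names = FALSE)
  df <- read_calibration_pairs(tmp)
  expect_named(df, c("x_raw", "y_ref"))
  write.csv(data.frame(a = 1:4, b = 1:4), tmp, row.names = FALSE)
  expect_error(read_calibration_pairs(tmp), "x_raw")
})
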