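test_that("a silent trace yields no grasp events", {
  tr <- grasp_trace(list(index = rep(0, 100), middle = rep(0, 100)), 20)
  expect_length(detect_grasps(tr), 0)
})

test_that("six simulated grasps are detected as six events", {
  sim <- simulate_trace(trace_spec(
    turgor_kPa = c(272, 249, 40, 63, 180, 220), seed = 8))
  ev <- detect_grasps(sim$trace, on_kPa = 20, min_duration_s = 1)
  expect_length(ev, 6)
  plateaus <- vapply(ev, `[[`, numeric(1), "pressure_kPa")
  expect_equal(plateaus, sim$truth$turgor_kPa, tolerance = 0.05)
})

test_that("grasp events respect the minimum duration", {
  n <- 200
  ch <- rep(0, n); ch[100:104] <- 300  # 0.25 s blip at 20 Hz
  tr <- grasp_trace(list(index = ch), 20)
  expect_length(detect_grasps(tr, on_kPa = 20, min_duration_s = 1), 0)
  expect_length(detect_grasps(tr, on_kPa = 20, min_duration_s = 0.2), 1)
})

test_that("grasp detection count matches the configured pulse count", {
  # amplitudes >= 1.5x threshold, durations >= 2x minimum, many seeds
  on <- 20
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(2:6, 1)
    amps <- runif(k, 1.5 * on, 300)
    sim <- simulate_trace(trace_spec(turgor_kPa = amps, pulse_s = 2.5,
                                     gap_s = 1.5, seed = seed))
    ev <- detect_grasps(sim$trace, on_kPa = on, min_duration_s = 1)
    expect_length(ev, k)
  }
})

test_that("low-contact fingers are excluded from the grasp pressure", {
  ev <- structure(list(plateaus_kPa = c(index = 200, middle = 195,
                                        ring = 190, little = 40)),
                  class = "grasp_event")
  expect_equal(valid_fingers(ev, 0.5), c("index", "middle", "ring"))
  one <- structure(list(plateaus_kPa = c(index = 150)), class = "grasp_event")
  expect_equal(valid_fingers(one), "index")
  all_eq <- structure(list(plateaus_kPa = c(a = 80, b = 80, c = 80)),
                      class = "grasp_event")
  expect_equal(valid_fingers(all_eq), c("a", "b", "c"))

  # end to end: one finger with poor contact does not bias the estimate
  sim <- simulate_trace(trace_spec(
    turgor_kPa = 250,
    contact_quality = c(index = 1, middle = 1, ring = 1, little = 0.2),
    seed = 4))
  ev2 <- detect_grasps(sim$trace)[[1]]
  expect_equal(ev2$valid_fingers, c("index", "middle", "ring"))
  expect_equal(ev2$pressure_kPa, 250, tolerance = 0.02)
})

test_that("turgor pressure maps onto the documented ripeness bands", {
  expect_equal(as.character(classify_ripeness(272)), "unripe")
  expect_equal(as.character(classify_ripeness(63)), "ripe")
  expect_equal(as.character(classify_ripeness(5)), "inadequate")
  expect_equal(as.character(classify_ripeness(129)), "ripening")
  # total monotone partition of [0, Inf)
  p <- seq(0, 500, by = 0.5)
  cls <- classify_ripeness(p)
  expect_false(anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_true(all(attr(classify_ripeness(c(350, 450)), "out_of_range") ==
                    c(FALSE, TRUE)))
  expect_error(classify_ripeness(-1), "non-negative")
})

test_that("reference fruit averages classify as their ripeness labels", {
  ref <- fruit_turgor_reference()
  tomato <- ref[ref$fruit == "tomato", ]
  expect_equal(as.character(classify_ripeness(tomato$average_kPa)),
               c("unripe", "unripe", "ripening", "ripe"))
})

test_that("measurement summaries report mean, extrema and sample sd", {
  s <- summarize_measurements(rep(100, 10))
  expect_equal(s$sd, 0)
  vals <- c(275, 271, rep(272, 28))
  s2 <- summarize_measurements(vals)
  expect_equal(s2$average, mean(vals))
  expect_equal(s2$max, 275)
  expect_equal(s2$min, 271)
  expect_equal(s2$n, 30)
  expect_error(summarize_measurements(5), "at least 2")

  # simulator configured to a reference tomato reproduces its summary
  set.seed(10)
  draws <- pmax(0, rnorm(30, 272, 1.7))
  s3 <- summarize_measurements(draws)
  expect_lt(abs(s3$average - 272), 3 * 1.7)
})

test_that("the quality score is a bounded, scale-invariant weighted mean", {
  f <- c(pressure_kPa = 60)
  w <- c(pressure_kPa = 1)
  r <- list(pressure_kPa = c(20, 100))
  expect_equal(quality_score(f, w, r), 1)
  expect_false(quality_alert(quality_score(f, w, r), 0.5))

  at_limit <- c(pressure_kPa = 20)
  expect_equal(quality_score(at_limit, w, r), 0)
  expect_true(quality_alert(0, 0.5))

  two <- c(a = 5, b = 0)
  wr <- c(a = 3, b = 1)
  rr <- list(a = c(0, 10), b = c(2, 4))  # a at centre: 1; b outside: 0
  expect_equal(quality_score(two, wr, rr), 0.75)
  expect_equal(quality_score(two, wr * 7, rr), 0.75)  # weight rescaling

  set.seed(2)
  for (i in 1:20) {
    x <- c(a = runif(1, -5, 15), b = runif(1, 0, 6))
    s <- quality_score(x, wr, rr)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(quality_score(x, wr * runif(1, 0.1, 9), rr), s)
  }
})

test_that("traces round-trip through CSV, with optional raw conversion", {
  sim <- simulate_trace(trace_spec(turgor_kPa = c(100, 200), seed = 6))
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- sim$trace$channels
  df <- cbind(t_s = (seq_len(nrow(df)) - 1) / sim$trace$sample_rate_hz, df)
  write.csv(df, tmp, row.names = FALSE)
  tr <- read_grasp_trace(tmp)
  expect_equal(tr$sample_rate_hz, sim$trace$sample_rate_hz)
  expect_equal(tr$channels, sim$trace$channels)

  # raw-volt columns pass through a calibration model
  m <- calibration_model("linear", c(1, 0), valid_range = c(0, 10))
  raw <- data.frame(t_s = seq(0, 1, by = 0.1), index = rep(2, 11))
  write.csv(raw, tmp, row.names = FALSE)
  tr2 <- read_grasp_trace(tmp, calibration = m)
  expect_equal(tr2$channels$index, rep(kgfcm2_to_kpa(2), 11))
})
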