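test_that("pure noise produces no events at a 5-sigma threshold", {
  set.seed(21)
  tr <- structure(list(times_s = seq(0, 1, by = 2e-6),
                       current_uA = rnorm(500001, 0, 0.02),
                       sample_rate_hz = 5e5, ledger = NULL,
                       pitch_s = 140 / 8e4),
                  class = "signal_trace")
  expect_lte(nrow(detect_events(tr, 0.1)), 1)
})

test_that("threshold above the largest amplitude yields no events", {
  st <- quick_stream(30, lam = 0.5, seed = 4)
  tr <- synthesize(st, trace_config(noise_sd_uA = 0), seed = 5)
  expect_equal(nrow(detect_events(tr, 10)), 0)
})

test_that("gate classification follows the interval rules and tie-breaks", {
  g <- gate_config(0.2, 0.4)
  expect_equal(classify_events(0, g), "empty")
  expect_equal(classify_events(0.45, g), "multi")
  expect_equal(classify_events(0.3, g), "single")
  # boundaries go to the higher-count class
  expect_equal(classify_events(0.2, g), "single")
  expect_equal(classify_events(0.4, g), "multi")
  # a gap between empty threshold and the single gate is ambiguous
  g2 <- gate_config(0.25, 0.4, empty_threshold_uA = 0.15)
  expect_equal(classify_events(0.2, g2), "ambiguous")
  expect_equal(classify_events(0.1, g2), "empty")
  expect_error(gate_config(0.4, 0.2))
})

test_that("gates serialize losslessly to JSON", {
  g <- gate_config(0.2345678901234, 0.4, target_classes = c("single"))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_gates(g, path)
  g2 <- read_gates(path)
  expect_equal(g2$lower_uA, g$lower_uA, tolerance = 1e-15)
  expect_equal(g2$target_classes, g$target_classes)
})

test_that("histogram-valley calibration splits well-separated modes", {
  set.seed(31)
  two <- c(rnorm(600, 0.2, 0.02), rnorm(400, 0.30, 0.02))
  g <- calibrate_gates(two, expected_classes = 2)
  expect_lt(abs(g$lower_uA - 0.25), 0.5 * 0.02)
  set.seed(32)
  three <- c(rnorm(500, 0.2, 0.015), rnorm(300, 0.32, 0.015),
             rnorm(200, 0.47, 0.02))
  truth <- rep(c("empty", "single", "multi"), c(500, 300, 200))
  g3 <- calibrate_gates(three, expected_classes = 3)
  acc <- mean(classify_events(three, g3) == truth)
  expect_gt(acc, 0.95)
  # deterministic given data
  expect_identical(calibrate_gates(three, 3), g3)
  expect_error(calibrate_gates(rep(0.3, 300)), "degenerate")
  set.seed(33)
  expect_error(calibrate_gates(rnorm(500, 0.3, 0.02)), "unimodal")
})

test_that("trigger scheduling honours dead time and the rate cap", {
  trg <- trigger_model(activation_delay_s = 1e-3, pulse_width_s = 5e-3,
                       max_rate_hz = 200)
  one <- data.frame(peak_time_s = 0.1, label = "single")
  s1 <- schedule_triggers(one, trg, "single")
  expect_true(s1$triggered)
  expect_equal(s1$pulse_time_s, 0.101)
  # two targets 1 ms apart: the second is missed
  two <- data.frame(peak_time_s = c(0.1, 0.101), label = "single")
  s2 <- schedule_triggers(two, trg, "single")
  expect_equal(s2$triggered, c(TRUE, FALSE))
  # sustained 200 Hz all-target stream fires every pulse, never faster
  ev <- data.frame(peak_time_s = seq(0, 0.995, by = 1 / 200),
                   label = "single")
  s3 <- schedule_triggers(ev, trg, "single")
  expect_true(all(s3$triggered))
  expect_true(all(diff(s3$pulse_time_s) >= 1 / 200 - 1e-9))
  # property: random streams never violate the spacing
  set.seed(41)
  for (i in 1:5) {
    evr <- data.frame(peak_time_s = sort(runif(200, 0, 1)),
                      label = sample(c("single", "multi", "empty"), 200,
                                     replace = TRUE))
    sr <- schedule_triggers(evr, trg, c("single", "multi"))
    pt <- sr$pulse_time_s[!is.na(sr$pulse_time_s)]
    if (length(pt) > 1) expect_true(all(diff(pt) >= 5e-3 - 1e-9))
    expect_true(all(sr$label[sr$triggered] %in% c("single", "multi")))
  }
})

test_that("screening accuracy is perfect without noise and degrades with it", {
  st <- quick_stream(250, lam = 0.5, seed = 6)
  acc <- vapply(c(0, 0.01, 0.02), function(ns) {
    tr <- synthesize(st, trace_config(noise_sd_uA = ns), seed = 7)
    ev <- if (ns == 0) screen_trace(tr, table_gates())
          else {
            ev0 <- detect_events(tr, 0.1)
            screen_trace(tr, calibrate_gates(ev0$amplitude_uA, 3))
          }
    mean(ev$label == coarse_truth(ev$true_class))
  }, 0)
  expect_equal(acc[1], 1)
  expect_gte(acc[1], acc[2])
  expect_gte(acc[2] + 0.005, acc[3])
  # calibrated screening stays in the high-nineties at the default noise
  expect_gt(acc[2], 0.95)
})
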