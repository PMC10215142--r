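fake_filtered <- function(values, fps = 30, channel = "red") {
  structure(list(values = values, fps = fps, channel = channel,
                 spec = bandpass_spec(), n_samples = length(values)),
            class = "filtered_series")
}

fake_stats <- function(ac, dc, channel = "red", n = 100L, start = 1L) {
  structure(list(ac = ac, dc = dc, n = n, channel = channel, start = start,
                 valid = TRUE),
            class = "window_stats")
}

test_that("window statistics use population sd on AC and raw mean on DC", {
  raw <- channel_series(rep(100, 10), 30, "red")
  filt <- fake_filtered(rep(0, 10))
  ws <- window_stats(filt, raw, 1, 10)
  expect_equal(ws$ac, 0)
  expect_equal(ws$dc, 100)

  filt <- fake_filtered(c(1, -1, 1, -1))
  raw4 <- channel_series(rep(50, 4), 30, "red")
  expect_equal(window_stats(filt, raw4, 1, 4)$ac, 1)  # mean 0, mean square 1
  expect_equal(window_stats(filt, raw4, 1, 4, sd_type = "sample")$ac,
               sqrt(4 / 3))

  expect_error(window_stats(filt, raw4, 2, 4), class = "spo2_bounds_error")
  expect_error(window_stats(filt, raw4, 1, 1), class = "spo2_parameter_error")
})

test_that("window statistics match the brute-force oracle", {
  set.seed(17)
  for (i in 1:50) {
    vals <- runif(100, 0, 255)
    ac_vals <- vals - mean(vals)
    ws <- window_stats(fake_filtered(ac_vals), channel_series(vals, 30, "red"),
                       1, 100)
    o <- oracle_window(ac_vals)
    expect_equal(ws$ac, o$sd, tolerance = 1e-12)
    expect_equal(ws$dc, oracle_window(vals)$mean, tolerance = 1e-12)
  }
})

test_that("ratio of ratios divides the two relative pulsatile amplitudes", {
  expect_equal(ratio_of_ratios(fake_stats(1, 100), fake_stats(1, 100, "blue"))$r, 1)
  expect_equal(ratio_of_ratios(fake_stats(2, 100), fake_stats(1, 50, "blue"))$r, 1)

  # global illumination scale cancels
  set.seed(2)
  for (k in c(0.25, 0.5, 2, 7)) {
    ac_r <- runif(1, 0.5, 3); dc_r <- runif(1, 80, 200)
    ac_b <- runif(1, 0.5, 3); dc_b <- runif(1, 80, 200)
    r1 <- ratio_of_ratios(fake_stats(ac_r, dc_r), fake_stats(ac_b, dc_b, "blue"))$r
    r2 <- ratio_of_ratios(fake_stats(k * ac_r, k * dc_r),
                          fake_stats(k * ac_b, k * dc_b, "blue"))$r
    expect_equal(r1, r2, tolerance = 1e-12)
  }

  expect_error(ratio_of_ratios(fake_stats(1, 0), fake_stats(1, 100, "blue")),
               class = "spo2_degenerate_signal")
  expect_error(ratio_of_ratios(fake_stats(1, 100), fake_stats(0, 100, "blue")),
               class = "spo2_no_pulse")
})

test_that("calibration maps ratios to clamped, triaged estimates", {
  sub <- calibration_model(125, 28, "subtractive")
  est <- apply_calibration(1, sub)
  expect_equal(est$value, 97)
  expect_equal(est$triage$label, "normal")
  expect_false(est$clamped)

  add <- calibration_model(97.61, 0.42, "additive")
  expect_equal(apply_calibration(0, add)$value, 97.61)

  est5 <- apply_calibration(5, sub)
  expect_equal(est5$raw_value, -15)
  expect_equal(est5$value, 0)
  expect_true(est5$clamped)

  # subtractive model is strictly decreasing in r
  rs <- seq(0, 2, by = 0.1)
  vals <- vapply(rs, function(r) apply_calibration(r, sub)$raw_value, 0)
  expect_true(all(diff(vals) < 0))

  # the additive comparison model never drops below its intercept for r >= 0
  vals_add <- vapply(seq(0, 5, by = 0.01),
                     function(r) apply_calibration(r, add)$raw_value, 0)
  expect_true(all(vals_add >= 97.61))
})

test_that("calibration fitting recovers the generating line", {
  r <- seq(0.5, 1.5, length.out = 12)
  y <- 125 - 28 * r
  fit <- fit_calibration(data.frame(r = r, spo2 = y), mode = "full")
  expect_equal(fit$a, 125, tolerance = 1e-9)
  expect_equal(fit$b, 28, tolerance = 1e-9)

  # fixed-intercept mode from a single pair: 125 - b = 97 so b = 28
  fit1 <- fit_calibration(data.frame(r = 1, spo2 = 97), mode = "fixed_a")
  expect_equal(fit1$b, 28)
  expect_equal(fit1$a, 125)

  expect_error(fit_calibration(data.frame(r = rep(1, 5), spo2 = 97 + 1:5),
                               mode = "full"),
               class = "spo2_rank_error")
})

test_that("triage follows the home-monitoring thresholds, severity-first", {
  expect_equal(classify_triage(95)$label, "normal")
  expect_equal(classify_triage(92)$label, "monitor")
  expect_equal(classify_triage(90)$label, "emergency")
  expect_equal(classify_triage(100)$label, "normal")
  # gap values resolve to the more severe neighbor
  expect_equal(classify_triage(94.5)$label, "monitor")
  expect_equal(classify_triage(90.5)$label, "emergency")
  expect_equal(classify_triage(90.0)$label, "emergency")
  expect_error(classify_triage(101), class = "spo2_range_error")
  expect_error(classify_triage(-1), class = "spo2_range_error")
})

test_that("stream estimation recovers a noiseless synthetic session", {
  s <- synth_series(scene_config(true_spo2 = 97))
  rep <- estimate_stream(s$red, s$blue)
  expect_equal(rep$summary, 97, tolerance = 0.5 / 97)
  expect_equal(rep$triage$label, "normal")
  expect_gt(rep$n_windows, 5)

  # halving illumination leaves the estimate unchanged (algebraic invariance)
  red2 <- channel_series(s$red$values / 2, s$red$fps, "red")
  blue2 <- channel_series(s$blue$values / 2, s$blue$fps, "blue")
  rep2 <- estimate_stream(red2, blue2)
  expect_equal(rep2$summary, rep$summary, tolerance = 1e-9)
  expect_equal(rep2$windows$r, rep$windows$r, tolerance = 1e-9)
})

test_that("pulseless input raises insufficient-data, not a crash", {
  const_r <- channel_series(rep(120, 900), 30, "red")
  const_b <- channel_series(rep(90, 900), 30, "blue")
  expect_error(estimate_stream(const_r, const_b),
               class = "spo2_insufficient_data")

  short <- synth_series(scene_config(duration_s = 2))
  expect_error(estimate_stream(short$red, short$blue),
               class = "spo2_insufficient_data")
})
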