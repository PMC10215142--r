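test_that("synthetic landmark backend round-trips embedded fixtures", {
  lm <- rect_landmarks(5, 3, 10, 4)
  f <- constant_frame(20, 30, c(100, 110, 120), landmarks = lm)
  got <- detect_landmarks(f)
  expect_s3_class(got, "landmark_set")
  expect_equal(got$points, lm$points)

  blank <- constant_frame(20, 30, c(0, 0, 0))
  expect_true(is_no_face(detect_landmarks(blank)))

  expect_error(detect_landmarks(f, backend = "nonexistent"), "backend")
})

test_that("short detection gaps are carried forward, long ones are not", {
  lm <- rect_landmarks(5, 3, 10, 4)
  good <- constant_frame(20, 30, c(100, 100, 100), landmarks = lm)
  bad <- constant_frame(20, 30, c(100, 100, 100))
  frames <- rep(list(good), 100)
  frames[[50]] <- bad
  fs <- frame_sequence(frames, fps = 30)
  out <- detect_landmarks_sequence(fs)
  expect_s3_class(out[[50]], "landmark_set")
  expect_equal(out[[50]]$points, lm$points)

  # a gap longer than one second of frames becomes no-face
  frames_long <- c(rep(list(good), 5), rep(list(bad), 40), rep(list(good), 5))
  out2 <- detect_landmarks_sequence(frame_sequence(frames_long, fps = 30))
  expect_s3_class(out2[[10]], "landmark_set")   # within the 30-frame grace
  expect_true(is_no_face(out2[[40]]))           # beyond it
})

test_that("forehead rectangle rasterizes to the half-open pixel count", {
  lm <- rect_landmarks(5, 3, 10, 4)
  roi <- forehead_roi(lm, c(20, 30))
  expect_equal(roi$pixel_count, 40)
  expect_equal(roi$pixel_count,
               oracle_pixels_inside(forehead_points(lm)[1:4, ], 20, 30))

  # partially outside: clipped but non-empty
  lm_part <- rect_landmarks(-4, 3, 10, 4)
  roi_part <- forehead_roi(lm_part, c(20, 30))
  expect_equal(roi_part$pixel_count, 24)

  # entirely outside: degenerate
  lm_out <- rect_landmarks(40, 3, 10, 4)
  expect_error(forehead_roi(lm_out, c(20, 30)), class = "spo2_degenerate_roi")

  # collinear forehead points: degenerate polygon
  pts <- cbind(seq(0, 12), 5)[rep(1:13, length.out = 13), ]
  lm_line <- landmark_set(rbind(matrix(0, 68, 2), pts))
  expect_error(forehead_roi(lm_line, c(20, 30)), class = "spo2_degenerate_roi")
})

test_that("channel extraction is the masked mean, order-resolved", {
  lm <- rect_landmarks(5, 3, 10, 4)
  n <- 60
  f0 <- constant_frame(20, 30, c(100, 50, 80), landmarks = lm)
  fs <- frame_sequence(rep(list(f0), n), fps = 30)
  roi <- forehead_roi(lm, c(20, 30))
  s <- extract_channel_series(fs, roi)
  expect_equal(s$red$values, rep(100, n))
  expect_equal(s$blue$values, rep(80, n))
  expect_equal(stats::sd(s$red$values), 0)

  # BGR source with swapped planes gives the identical red series
  f_bgr <- constant_frame(20, 30, c(80, 50, 100), landmarks = lm)
  fs_bgr <- frame_sequence(rep(list(f_bgr), n), fps = 30, channel_order = "BGR")
  s2 <- extract_channel_series(fs_bgr, roi)
  expect_identical(s2$red$values, s$red$values)
  expect_identical(s2$blue$values, s$blue$values)
})

test_that("extraction matches a brute-force masked mean on random input", {
  set.seed(21)
  lm <- rect_landmarks(2, 2, 9, 6)
  roi <- forehead_roi(lm, c(15, 15))
  for (i in 1:5) {
    f <- array(runif(15 * 15 * 3, 0, 255), dim = c(15, 15, 3))
    fs <- frame_sequence(list(f), fps = 30)
    s <- extract_channel_series(fs, roi)
    expect_equal(s$red$values, oracle_masked_mean(f[, , 1], roi$mask),
                 tolerance = 1e-9)
    expect_equal(s$blue$values, oracle_masked_mean(f[, , 3], roi$mask),
                 tolerance = 1e-9)
  }
})

test_that("pixels outside the mask never influence the series", {
  set.seed(4)
  lm <- rect_landmarks(5, 3, 10, 4)
  roi <- forehead_roi(lm, c(20, 30))
  f <- array(runif(20 * 30 * 3, 0, 255), dim = c(20, 30, 3))
  f2 <- f
  for (ch in 1:3) f2[, , ch][!roi$mask] <- runif(sum(!roi$mask), 0, 255)
  s1 <- extract_channel_series(frame_sequence(list(f), 30), roi)
  s2 <- extract_channel_series(frame_sequence(list(f2), 30), roi)
  expect_identical(s1$red$values, s2$red$values)
  expect_identical(s1$blue$values, s2$blue$values)
})

test_that("a sinusoidal red plane is recovered through the full extract path", {
  cfg <- scene_config(duration_s = 4, true_spo2 = 97, quantize = TRUE)
  scene <- synth_frames(cfg)
  masks <- forehead_roi(scene$landmarks, scene$frames$dims[1:2])
  s <- extract_channel_series(scene$frames, masks)
  truth <- synth_series(scene_config(duration_s = 4, true_spo2 = 97))
  expect_lt(max(abs(s$red$values - truth$red$values)), 0.5)
  expect_lt(max(abs(s$blue$values - truth$blue$values)), 0.5)
})
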