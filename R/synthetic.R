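# Synthetic pulsatile scenes with known ground truth. The generator
# realizes the signal model the ratio-of-ratios pipeline assumes: each
# channel is a DC level plus a cardiac-frequency pulsatile component,
# scaled by a global illumination factor, with optional additive white
# noise and 8-bit quantization. Inverting the calibration line
# SpO2 = a - b*R gives the target ratio, and the red AC amplitude is
# chosen so the analytic (AC/DC) ratio of the two channels equals it
# exactly.

#' Configuration of a synthetic pulsatile scene
#'
#' Defaults describe a realistic resting measurement: a 30-second capture
#' at 30 fps of a subject at 72 bpm with healthy saturation, forehead DC
#' levels of 150 bpp (red) and 100 bpp (blue), a blue pulsatile amplitude
#' of 1 bpp (a typical ~1 percent perfusion modulation), no noise, and no
#' quantization.
#'
#' @param duration_s scene length in seconds.
#' @param fps frame rate.
#' @param heart_rate_bpm cardiac frequency in beats per minute, in (30, 250).
#' @param true_spo2 ground-truth saturation in percent; ignored when
#'   `true_r` is given.
#' @param true_r ground-truth ratio-of-ratios; overrides `true_spo2`.
#' @param calibration the [calibration_model()] inverted to turn
#'   `true_spo2` into the target ratio (default a = 125, b = 28).
#' @param dc_red,dc_blue mean channel levels in bpp.
#' @param ac_blue blue pulsatile amplitude in bpp.
#' @param illumination global multiplicative scale k > 0 on both channels.
#' @param noise_sd additive white Gaussian noise sd in bpp.
#' @param quantize logical; round and clip rendered values to 8-bit.
#' @param waveform `"sinusoid"` (default) or `"dicrotic"` (adds a second
#'   harmonic, a crude dicrotic-notch-like pulse for robustness tests).
#' @param seed RNG seed, always recorded in the ground truth.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(duration_s = 30, fps = 30, heart_rate_bpm = 72,
                         true_spo2 = 97, true_r = NULL,
                         calibration = default_calibration(),
                         dc_red = 150, dc_blue = 100, ac_blue = 1,
                         illumination = 1, noise_sd = 0, quantize = FALSE,
                         waveform = c("sinusoid", "dicrotic"), seed = 1L) {
  waveform <- match.arg(waveform)
  if (heart_rate_bpm <= 30 || heart_rate_bpm >= 250)
    stop_classed("spo2_parameter_error",
                 "heart rate %.3g bpm outside the plausible (30, 250) range",
                 heart_rate_bpm)
  if (illumination <= 0)
    stop_classed("spo2_parameter_error", "illumination scale must be > 0")
  if (duration_s <= 0 || fps <= 0 || dc_red <= 0 || dc_blue <= 0 ||
      ac_blue <= 0 || noise_sd < 0)
    stop_classed("spo2_parameter_error", "invalid scene configuration")
  if (is.null(true_r)) {
    if (calibration$mode != "subtractive")
      stop_classed("spo2_parameter_error",
                   "spo2 inversion requires a subtractive calibration")
    true_r <- (calibration$a - true_spo2) / calibration$b
    if (true_r <= 0)
      stop_classed("spo2_parameter_error",
                   "true_spo2 %.3g is at or above the calibration intercept",
                   true_spo2)
  } else {
    true_spo2 <- apply_calibration(true_r, calibration)$value
  }
  cfg <- structure(list(duration_s = duration_s, fps = fps,
                        heart_rate_bpm = heart_rate_bpm,
                        true_spo2 = true_spo2, true_r = true_r,
                        calibration = calibration,
                        dc_red = dc_red, dc_blue = dc_blue, ac_blue = ac_blue,
                        illumination = illumination, noise_sd = noise_sd,
                        quantize = quantize, waveform = waveform,
                        seed = as.integer(seed)),
                   class = "scene_config")
  # Red amplitude follows from the target ratio: ac_r/dc_r = r * ac_b/dc_b.
  cfg$ac_red <- true_r * (ac_blue / dc_blue) * dc_red
  k <- illumination
  if (!quantize &&
      (k * (dc_red + cfg$ac_red) > 255 || k * (dc_red - cfg$ac_red) < 0 ||
       k * (dc_blue + ac_blue) > 255 || k * (dc_blue - ac_blue) < 0))
    stop_classed("spo2_parameter_error",
                 "configured amplitudes clip outside [0, 255]; enable quantize to allow clipping")
  cfg
}

# Unit-amplitude pulse waveform at phase vector ph (radians).
pulse_wave <- function(ph, waveform) {
  if (waveform == "sinusoid") sin(ph)
  else (sin(ph) + 0.3 * sin(2 * ph + pi / 4)) / 1.3
}

#' Generate red and blue channel series with known ground truth
#'
#' `channel(t) = k * (dc + ac * w(2 * pi * f_hr * t)) + noise`, with the
#' red amplitude set so the analytic AC/DC ratio-of-ratios equals the
#' configured `true_r` exactly. Deterministic given the config (including
#' seed).
#'
#' @param config a [scene_config()].
#' @return list with `red` and `blue` ([channel_series()]) and
#'   `ground_truth` (`true_r`, `true_spo2`, per-channel `ac`/`dc`,
#'   `cardiac_hz`, `seed`).
#' @export
synth_series <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  n <- round(config$duration_s * config$fps)
  t <- (seq_len(n) - 1) / config$fps
  f <- config$heart_rate_bpm / 60
  ph <- 2 * pi * f * t
  k <- config$illumination
  w <- pulse_wave(ph, config$waveform)
  red <- k * (config$dc_red + config$ac_red * w)
  blue <- k * (config$dc_blue + config$ac_blue * w)
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    red <- red + stats::rnorm(n, sd = config$noise_sd)
    blue <- blue + stats::rnorm(n, sd = config$noise_sd)
  }
  if (config$quantize) {
    red <- round(pmin(255, pmax(0, red)))
    blue <- round(pmin(255, pmax(0, blue)))
  } else {
    red <- pmin(255, pmax(0, red))
    blue <- pmin(255, pmax(0, blue))
  }
  list(red = channel_series(red, config$fps, "red"),
       blue = channel_series(blue, config$fps, "blue"),
       ground_truth = list(true_r = config$true_r,
                           true_spo2 = config$true_spo2,
                           ac_red = config$ac_red, dc_red = config$dc_red,
                           ac_blue = config$ac_blue, dc_blue = config$dc_blue,
                           illumination = k,
                           cardiac_hz = f, seed = config$seed))
}

#' Render a synthetic scene as a frame sequence
#'
#' Pixels inside `roi_rect` carry the synthetic red/blue waveforms on their
#' respective color planes (green held constant); everything outside is a
#' static background. A fixture [landmark_set()] whose forehead points
#' trace `roi_rect` is attached to every frame (for the `"synthetic"`
#' landmark backend) and returned, so the full
#' detect-landmarks / forehead-ROI / extract path runs on the output.
#'
#' @param config a [scene_config()].
#' @param frame_dims `c(height, width)` in pixels.
#' @param roi_rect `c(x, y, width, height)`, 0-based integer pixel
#'   coordinates of the forehead patch; must lie inside the frame.
#' @return list with `frames` (a [frame_sequence()]), `landmarks` (the
#'   fixture `landmark_set`), and `ground_truth`.
#' @export
synth_frames <- function(config, frame_dims = c(60, 80),
                         roi_rect = c(20, 10, 40, 16)) {
  stopifnot(inherits(config, "scene_config"))
  h <- as.integer(frame_dims[1]); w <- as.integer(frame_dims[2])
  x0 <- roi_rect[1]; y0 <- roi_rect[2]
  rw <- roi_rect[3]; rh <- roi_rect[4]
  if (x0 < 0 || y0 < 0 || x0 + rw > w || y0 + rh > h || rw < 1 || rh < 1)
    stop_classed("spo2_parameter_error", "roi_rect must lie inside the frame")

  quantize <- config$quantize
  series_cfg <- config
  series_cfg$quantize <- FALSE  # quantization happens at the pixel, below
  s <- synth_series(series_cfg)

  lm_fix <- rect_landmark_fixture(x0, y0, rw, rh, h, w)
  rows <- (y0 + 1):(y0 + rh)
  cols <- (x0 + 1):(x0 + rw)
  green_level <- config$illumination * (config$dc_red + config$dc_blue) / 2
  bg <- 60

  n <- length(s$red$values)
  frames <- vector("list", n)
  base <- array(bg, dim = c(h, w, 3))
  for (i in seq_len(n)) {
    f <- base
    f[rows, cols, 1] <- s$red$values[i]
    f[rows, cols, 2] <- green_level
    f[rows, cols, 3] <- s$blue$values[i]
    if (quantize) f[] <- round(pmin(255, pmax(0, f)))
    attr(f, "landmarks") <- lm_fix
    frames[[i]] <- f
  }
  list(frames = frame_sequence(frames, config$fps, "RGB"),
       landmarks = lm_fix,
       ground_truth = s$ground_truth)
}

# 81-point fixture whose 13 forehead points trace the given rectangle; the
# remaining 68 "face" points sit in a block below it.
rect_landmark_fixture <- function(x0, y0, rw, rh, h, w) {
  xs <- x0 + c(0, 0.25, 0.5, 0.75, 1) * rw
  top <- cbind(xs, y0)
  bottom <- cbind(xs, y0 + rh)
  sides <- rbind(c(x0, y0 + rh / 2), c(x0 + rw, y0 + rh / 2),
                 c(x0 + rw / 2, y0 + rh / 2))
  forehead <- rbind(top, bottom, sides)  # 13 points, hull = the rectangle
  stopifnot(nrow(forehead) == 13L)
  face_y <- min(h - 1, y0 + rh + 2)
  face <- cbind(x0 + (seq_len(68) - 1) %% 17 / 16 * rw,
                pmin(h - 1, face_y + (seq_len(68) - 1) %/% 17))
  landmark_set(rbind(face, forehead), source = "synthetic")
}

#' Simulate a measurement cohort and evaluate recovery
#'
#' For each synthetic subject, a ground-truth SpO2 is drawn uniformly from
#' `spo2_range`, a scene is generated at that truth, the full estimation
#' pipeline runs on it, and the (estimate, truth) pair is recorded.
#' Reproducible from the seed.
#'
#' @param n_subjects number of subjects, >= 1.
#' @param spo2_range `c(lo, hi)` percent; degenerate ranges allowed.
#' @param noise_sd per-channel additive noise sd in bpp.
#' @param seed cohort RNG seed.
#' @param config_template a [scene_config()] supplying everything except
#'   `true_spo2`, `noise_sd` and `seed`.
#' @return list with `pairs` (a [paired_readings()] of estimates vs.
#'   truths), `truths`, `estimates`, and per-subject `reports`.
#' @export
make_cohort <- function(n_subjects = 30, spo2_range = c(90, 99),
                        noise_sd = 0, seed = 1L,
                        config_template = scene_config()) {
  if (n_subjects < 1L)
    stop_classed("spo2_parameter_error", "need at least one subject")
  if (length(spo2_range) != 2L || spo2_range[1] > spo2_range[2] ||
      spo2_range[1] < 0 || spo2_range[2] > 100)
    stop_classed("spo2_parameter_error", "invalid spo2_range")
  set.seed(seed)
  truths <- stats::runif(n_subjects, spo2_range[1], spo2_range[2])
  subject_seeds <- sample.int(2^30, n_subjects)
  estimates <- numeric(n_subjects)
  reports <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- config_template
    cfg_i <- scene_config(duration_s = cfg$duration_s, fps = cfg$fps,
                          heart_rate_bpm = cfg$heart_rate_bpm,
                          true_spo2 = truths[i],
                          calibration = cfg$calibration,
                          dc_red = cfg$dc_red, dc_blue = cfg$dc_blue,
                          ac_blue = cfg$ac_blue,
                          illumination = cfg$illumination,
                          noise_sd = noise_sd, quantize = cfg$quantize,
                          waveform = cfg$waveform, seed = subject_seeds[i])
    s <- synth_series(cfg_i)
    rep_i <- estimate_stream(s$red, s$blue, cfg$calibration)
    estimates[i] <- rep_i$summary
    reports[[i]] <- rep_i
  }
  list(pairs = paired_readings(estimates, truths),
       truths = truths, estimates = estimates, reports = reports)
}
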