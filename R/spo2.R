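# The defining computation: windowed AC/DC statistics, the ratio-of-ratios
# R = (AC_red/DC_red) / (AC_blue/DC_blue), and its linear calibration to
# SpO2. Red light absorption differs strongly between oxygenated and
# deoxygenated hemoglobin while blue is comparatively insensitive, so R
# falls as saturation rises and a decreasing linear map SpO2 = A - B*R
# calibrates it; the reference fit used throughout is A = 125, B = 28.

#' Default calibrated coefficients (A = 125, B = 28, subtractive)
#' @return a [calibration_model()].
#' @export
default_calibration <- function() calibration_model(125, 28, "subtractive")

# AC thresholds below which a window is declared pulseless rather than
# divided by ~0 (bpp scale; numerical residue of filtering a constant is
# orders of magnitude smaller).
NO_PULSE_AC <- 1e-6

#' Windowed AC/DC statistics of one channel
#'
#' AC is the population standard deviation (divide by N, not N - 1) of the
#' bandpass-filtered window; DC is the mean of the raw, unfiltered window.
#' The two come from different views of the same samples because the
#' bandpass removes the mean that the ratio-of-ratios still needs.
#'
#' @param series_ac a `filtered_series` (AC pathway).
#' @param series_raw the matching raw [channel_series()] (DC pathway).
#' @param start 1-based first sample of the window.
#' @param n window length in samples (default 100).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return object of class `window_stats`: `ac`, `dc`, `n`, `channel`,
#'   `start`, `valid` (FALSE when the window contains gap samples).
#' @export
window_stats <- function(series_ac, series_raw, start, n = 100L,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(series_ac, "filtered_series"),
            inherits(series_raw, "channel_series"))
  if (n < 2L)
    stop_classed("spo2_parameter_error", "window length must be at least 2")
  if (start < 1L || start + n - 1L > series_ac$n_samples ||
      start + n - 1L > series_raw$n_samples)
    stop_classed("spo2_bounds_error",
                 "window [%d, %d] overruns the series", start, start + n - 1L)
  idx <- start:(start + n - 1L)
  ac_win <- series_ac$values[idx]
  raw_win <- series_raw$values[idx]
  valid <- !anyNA(ac_win) && !anyNA(raw_win)
  if (valid) {
    m <- mean(ac_win)
    ss <- sum((ac_win - m)^2)
    ac <- sqrt(ss / if (sd_type == "population") n else n - 1L)
    dc <- mean(raw_win)
  } else {
    ac <- NA_real_; dc <- NA_real_
  }
  structure(list(ac = ac, dc = dc, n = as.integer(n),
                 channel = series_raw$channel, start = as.integer(start),
                 valid = valid),
            class = "window_stats")
}

#' Ratio of ratios of a red/blue window pair
#'
#' `r = (AC_red / DC_red) / (AC_blue / DC_blue)`: the wavelength-contrast
#' statistic that maps to SpO2. It is dimensionless and invariant to any
#' global illumination scale applied to both channels. A window whose blue
#' AC is (numerically) zero carries no pulse and raises a classed
#' `spo2_no_pulse` condition that stream processing catches and skips; a
#' nonpositive DC raises `spo2_degenerate_signal`.
#'
#' @param red,blue `window_stats` for the two channels.
#' @return object of class `ratio_measurement`: `r` plus both stats.
#' @export
ratio_of_ratios <- function(red, blue) {
  stopifnot(inherits(red, "window_stats"), inherits(blue, "window_stats"))
  if (!red$valid || !blue$valid)
    stop_classed("spo2_no_pulse", "window contains invalid (gap) samples")
  if (red$dc <= 0 || blue$dc <= 0)
    stop_classed("spo2_degenerate_signal",
                 "window DC must be positive (red %.3g, blue %.3g)",
                 red$dc, blue$dc)
  if (blue$ac < NO_PULSE_AC)
    stop_classed("spo2_no_pulse",
                 "blue AC %.3g bpp below pulse threshold: unusable window",
                 blue$ac)
  r <- (red$ac / red$dc) / (blue$ac / blue$dc)
  structure(list(r = r, red = red, blue = blue), class = "ratio_measurement")
}

#' Linear SpO2 calibration model
#'
#' Subtractive convention: `SpO2 = a - b * r` (decreasing in r; the form
#' used by this pipeline, reference fit a = 125, b = 28). Additive
#' convention: `SpO2 = a + b * r`, provided for comparison with an earlier
#' red/blue formula `SpO2 = 97.61 + 0.42 * r`, whose output can never fall
#' below its intercept for nonnegative r.
#'
#' @param a intercept: SpO2 in percent at r = 0.
#' @param b slope magnitude in percent per unit r; must be > 0 so the
#'   subtractive model is decreasing and the additive one increasing.
#' @param mode `"subtractive"` (default) or `"additive"`.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(a = 125, b = 28,
                              mode = c("subtractive", "additive")) {
  mode <- match.arg(mode)
  if (!is.finite(a) || !is.finite(b))
    stop_classed("spo2_parameter_error", "coefficients must be finite")
  if (b <= 0)
    stop_classed("spo2_parameter_error",
                 "b must be positive (the sign lives in the mode)")
  structure(list(a = a, b = b, mode = mode), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  op <- if (x$mode == "subtractive") "-" else "+"
  cat(sprintf("<calibration_model> SpO2 = %.4g %s %.4g * R\n", x$a, op, x$b))
  invisible(x)
}

#' Map a ratio measurement to a calibrated SpO2 estimate
#'
#' Values outside \[0, 100\] percent are clamped and flagged rather than
#' erroring; the triage category of the (clamped) value is attached.
#'
#' @param r a `ratio_measurement`, or a bare nonnegative number.
#' @param model a [calibration_model()].
#' @return object of class `spo2_estimate`: `value` (percent), `raw_value`,
#'   `clamped`, `triage`, `r`, `window_start`.
#' @export
apply_calibration <- function(r, model = default_calibration()) {
  stopifnot(inherits(model, "calibration_model"))
  window_start <- NA_integer_
  if (inherits(r, "ratio_measurement")) {
    window_start <- r$red$start
    r <- r$r
  }
  if (!is.numeric(r) || !is.finite(r))
    stop_classed("spo2_parameter_error", "ratio must be a finite number")
  raw <- if (model$mode == "subtractive") model$a - model$b * r
         else model$a + model$b * r
  value <- min(100, max(0, raw))
  structure(list(value = value, raw_value = raw, clamped = value != raw,
                 triage = classify_triage(value), r = r,
                 window_start = window_start),
            class = "spo2_estimate")
}

#' @export
print.spo2_estimate <- function(x, ...) {
  cat(sprintf("<spo2_estimate> %.2f%% (%s)%s\n", x$value, x$triage$label,
              if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Fit the linear calibration from paired (r, reference SpO2) readings
#'
#' Ordinary least squares on `SpO2 = a - b * r`. In `"fixed_a"` mode
#' (the default, used to reproduce the reference fit) the intercept is held
#' at `a` and only the slope is estimated; `"full"` mode estimates both and
#' requires at least two distinct r values.
#'
#' @param pairs data frame (or list) with numeric columns `r` and `spo2`.
#' @param mode `"fixed_a"` or `"full"`.
#' @param a fixed intercept for `"fixed_a"` mode (default 125).
#' @return a [calibration_model()] with attributes `residuals` and `n`.
#' @export
fit_calibration <- function(pairs, mode = c("fixed_a", "full"), a = 125) {
  mode <- match.arg(mode)
  r <- as.numeric(pairs$r); y <- as.numeric(pairs$spo2)
  if (length(r) != length(y) || length(r) < 1L || anyNA(r) || anyNA(y))
    stop_classed("spo2_parameter_error",
                 "pairs must supply equal-length, complete r and spo2 columns")
  if (mode == "fixed_a") {
    if (sum(r^2) == 0)
      stop_classed("spo2_parameter_error", "cannot fit slope: all r are zero")
    b <- sum(r * (a - y)) / sum(r^2)
  } else {
    if (length(r) < 2L || length(unique(r)) < 2L)
      stop_classed("spo2_rank_error",
                   "full fit needs at least two pairs with distinct r")
    fit <- stats::lm.fit(cbind(1, r), y)
    a <- unname(fit$coefficients[1])
    b <- -unname(fit$coefficients[2])
  }
  model <- calibration_model(a, b, "subtractive")
  attr(model, "residuals") <- y - (a - b * r)
  attr(model, "n") <- length(r)
  model
}

#' Triage category of an SpO2 value
#'
#' Home-monitoring guidance: at or above 95 percent is normal; 91-94
#' percent warrants monitoring; at or below 90 percent is an emergency.
#' Non-integer values falling in the gaps between the printed bands are
#' assigned to the more severe neighbor (safety-first), so the effective
#' boundaries are value >= 95 normal, 91 <= value < 95 monitor,
#' value < 91 emergency.
#'
#' @param value SpO2 percentage in \[0, 100\].
#' @return object of class `triage_category` with `label` in
#'   `"normal"`, `"monitor"`, `"emergency"` and the `rule` applied.
#' @export
classify_triage <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 100)
    stop_classed("spo2_range_error",
                 "SpO2 value must be a single number in [0, 100]")
  label <- if (value >= 95) "normal" else if (value >= 91) "monitor"
           else "emergency"
  rule <- switch(label,
                 normal = ">= 95",
                 monitor = "91-94 (gap 94-95 resolved toward severity)",
                 emergency = "<= 90 (gap 90-91 resolved toward severity)")
  structure(list(label = label, rule = rule), class = "triage_category")
}

#' Sliding-window SpO2 estimation over a red/blue series pair
#'
#' The full measurement: bandpass both channels, slide a window (default
#' 100 samples, hop 50) over the aligned series, compute AC/DC stats and
#' the ratio-of-ratios per window, calibrate each to SpO2, and summarize
#' the session as the median of valid window estimates. Windows within one
#' second of either end are excluded (zero-phase filter edge transients),
#' and pulseless or gap windows are skipped, not fatal. Fewer than one
#' valid window raises a classed `spo2_insufficient_data` condition.
#'
#' @param red,blue aligned [channel_series()] at the same fps.
#' @param model a [calibration_model()].
#' @param window window length in samples (default 100).
#' @param hop hop between window starts in samples (default `window / 2`).
#' @param band a [bandpass_spec()].
#' @param edge_s seconds of filtered output excluded at each end (default 1).
#' @return object of class `spo2_report`: `summary` (median SpO2, percent),
#'   `triage` of the summary, `windows` (data frame: start, r, spo2, raw,
#'   clamped, triage), `n_windows`, `n_rejected`, and the full
#'   configuration used.
#' @export
estimate_stream <- function(red, blue, model = default_calibration(),
                            window = 100L, hop = NULL,
                            band = bandpass_spec(), edge_s = 1) {
  stopifnot(inherits(red, "channel_series"), inherits(blue, "channel_series"))
  if (red$n_samples != blue$n_samples || red$fps != blue$fps)
    stop_classed("spo2_parameter_error",
                 "red and blue series must be aligned (same length and fps)")
  if (is.null(hop)) hop <- max(1L, window %/% 2L)
  n <- red$n_samples
  margin <- as.integer(ceiling(red$fps * edge_s))
  first <- margin + 1L
  last <- n - window + 1L - margin
  if (last < first)
    stop_classed("spo2_insufficient_data",
                 "series of %d samples cannot host a %d-sample window with %d-sample edge margins",
                 n, window, margin)

  red_f <- bandpass(red, band)
  blue_f <- bandpass(blue, band)

  starts <- seq.int(first, last, by = hop)
  rows <- vector("list", length(starts))
  n_rejected <- 0L
  for (k in seq_along(starts)) {
    s <- starts[k]
    est <- tryCatch({
      rr <- ratio_of_ratios(window_stats(red_f, red, s, window),
                            window_stats(blue_f, blue, s, window))
      apply_calibration(rr, model)
    }, spo2_no_pulse = function(e) NULL,
       spo2_degenerate_signal = function(e) NULL)
    if (is.null(est)) {
      n_rejected <- n_rejected + 1L
      next
    }
    rows[[k]] <- data.frame(start = s, r = est$r, spo2 = est$value,
                            raw = est$raw_value, clamped = est$clamped,
                            triage = est$triage$label)
  }
  windows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(windows) || nrow(windows) == 0L)
    stop_classed("spo2_insufficient_data",
                 "no valid window: all %d windows were pulseless or invalid",
                 length(starts))
  summary_value <- stats::median(windows$spo2)
  structure(list(summary = summary_value,
                 triage = classify_triage(summary_value),
                 windows = windows,
                 n_windows = nrow(windows),
                 n_rejected = n_rejected,
                 model = model, band = band,
                 window = as.integer(window), hop = as.integer(hop),
                 fps = red$fps),
            class = "spo2_report")
}

#' @export
print.spo2_report <- function(x, ...) {
  cat(sprintf("<spo2_report> SpO2 %.2f%% (%s) from %d windows (%d rejected)\n",
              x$summary, x$triage$label, x$n_windows, x$n_rejected))
  invisible(x)
}
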