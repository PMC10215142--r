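# Cardiac-band filtering of the raw channel series. The pulsatile (AC)
# component lives at the heart-rate frequency; the default passband
# 0.7-4 Hz covers 42-240 beats per minute, the standard rPPG band. The
# filter is a Butterworth bandpass applied forward-backward (zero phase),
# so red and blue stay aligned and per-frequency gain cancels in the
# ratio-of-ratios.

#' Bandpass filter specification
#'
#' @param low_hz lower cutoff in Hz, > 0 (default 0.7).
#' @param high_hz upper cutoff in Hz, > `low_hz` (default 4.0).
#' @param order Butterworth order (default 4).
#' @param design filter family; only `"butterworth"` is provided.
#' @return object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 0.7, high_hz = 4.0, order = 4L,
                          design = "butterworth") {
  if (!is.numeric(low_hz) || low_hz <= 0)
    stop_classed("spo2_spec_error", "low_hz must be > 0")
  if (!is.numeric(high_hz) || high_hz <= low_hz)
    stop_classed("spo2_spec_error", "high_hz must exceed low_hz")
  if (!is.numeric(order) || order < 1L)
    stop_classed("spo2_spec_error", "order must be a positive integer")
  if (design != "butterworth")
    stop_classed("spo2_spec_error", "unsupported filter design '%s'", design)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 design = design),
            class = "bandpass_spec")
}

#' Zero-phase bandpass of a channel series
#'
#' Applies the Butterworth bandpass forward and backward
#' (`signal::filtfilt`), preserving length and phase. The passband must lie
#' below the Nyquist frequency of the series. The mean (DC) component is
#' removed by the filter; callers that need it use
#' [detrend_preserving_dc()].
#'
#' @param series a [channel_series()].
#' @param spec a [bandpass_spec()].
#' @return object of class `filtered_series`: `values`, `fps`, `channel`,
#'   and the applied `spec` (provenance).
#' @export
bandpass <- function(series, spec = bandpass_spec()) {
  stopifnot(inherits(series, "channel_series"), inherits(spec, "bandpass_spec"))
  nyquist <- series$fps / 2
  if (spec$high_hz >= nyquist)
    stop_classed("spo2_spec_error",
                 "high cutoff %.3g Hz must be below the Nyquist frequency %.3g Hz",
                 spec$high_hz, nyquist)
  if (series$n_samples < 3L * spec$order)
    stop_classed("spo2_length_error",
                 "series too short to filter: %d samples < 3 x order (%d)",
                 series$n_samples, 3L * spec$order)
  bf <- signal::butter(spec$order,
                       c(spec$low_hz, spec$high_hz) / nyquist,
                       type = "pass")
  vals <- series$values
  # Remove the mean before filtering: the passband excludes DC anyway, and
  # a large offset would otherwise excite long edge transients in the
  # zero-padded forward-backward filter.
  vals <- vals - mean(vals, na.rm = TRUE)
  if (anyNA(vals)) {
    # Gap samples would propagate through the IIR state; filter the longest
    # runs separately is overkill here -- interpolate across short gaps.
    vals <- stats::approx(seq_along(vals), vals, xout = seq_along(vals),
                          rule = 2)$y
  }
  filtered <- signal::filtfilt(bf, vals)
  filtered[is.na(series$values)] <- NA_real_
  structure(list(values = filtered, fps = series$fps, channel = series$channel,
                 spec = spec, n_samples = length(filtered)),
            class = "filtered_series")
}

#' Split a series into its pulsatile part and its DC level
#'
#' The ratio-of-ratios needs both the AC (pulsatile) component and the DC
#' (mean) level of each channel. Because a bandpass removes the mean, the
#' two are taken from different views of the same window: AC from the
#' filtered series, DC from the raw, unfiltered one. This helper performs
#' the split over a whole series.
#'
#' @param series a [channel_series()].
#' @param spec a [bandpass_spec()].
#' @return list with `ac_part` (a `filtered_series`) and `dc_level`
#'   (mean of the unfiltered series).
#' @export
detrend_preserving_dc <- function(series, spec = bandpass_spec()) {
  list(ac_part = bandpass(series, spec),
       dc_level = mean(series$values, na.rm = TRUE))
}
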