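# Agreement metrics between contactless estimates and a reference
# pulse-oximeter: mean absolute error (the field's standard performance
# indicator) and maximum absolute error, plus packaged fixtures of the
# published validation readings.

#' Construct a paired-readings set
#'
#' @param estimates contactless SpO2 estimates in percent.
#' @param references reference-device SpO2 readings in percent.
#' @param labels optional per-pair labels (subject, day, ...).
#' @return object of class `paired_readings`.
#' @export
paired_readings <- function(estimates, references, labels = NULL) {
  if (length(estimates) != length(references))
    stop_classed("spo2_shape_error",
                 "estimates (%d) and references (%d) differ in length",
                 length(estimates), length(references))
  if (length(estimates) < 1L)
    stop_classed("spo2_parameter_error", "need at least one pair")
  vals <- c(estimates, references)
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0 | vals > 100))
    stop_classed("spo2_parameter_error",
                 "all readings must be numeric percentages in [0, 100]")
  structure(list(estimates = as.numeric(estimates),
                 references = as.numeric(references),
                 labels = labels, n = length(estimates)),
            class = "paired_readings")
}

#' Mean absolute error of paired readings
#'
#' `(1/n) * sum(|reference_i - estimate_i|)`, in percentage points.
#'
#' @param pairs a [paired_readings()].
#' @return mean absolute error (percent).
#' @export
mae <- function(pairs) {
  stopifnot(inherits(pairs, "paired_readings"))
  mean(abs(pairs$references - pairs$estimates))
}

#' Maximum absolute error of paired readings
#'
#' @param pairs a [paired_readings()].
#' @return largest absolute residual (percent).
#' @export
max_abs_error <- function(pairs) {
  stopifnot(inherits(pairs, "paired_readings"))
  max(abs(pairs$references - pairs$estimates))
}

#' Full agreement report
#'
#' @param pairs a [paired_readings()].
#' @return object of class `agreement_report`: `mae`, `max_abs_error`, `n`,
#'   and the per-pair `residuals` (reference minus estimate).
#' @export
agreement_report <- function(pairs) {
  stopifnot(inherits(pairs, "paired_readings"))
  structure(list(mae = mae(pairs),
                 max_abs_error = max_abs_error(pairs),
                 n = pairs$n,
                 residuals = pairs$references - pairs$estimates,
                 labels = pairs$labels),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d, MAE = %.3f%%, max |error| = %.3f%%\n",
              x$n, x$mae, x$max_abs_error))
  invisible(x)
}

#' Packaged validation readings: 30 daily paired measurements
#'
#' Thirty paired observations (six subjects over five days) of the
#' contactless forehead pipeline against a certified fingertip pulse
#' oximeter, transcribed from the published validation study this pipeline
#' implements. Columns: `day`, `tester`, `estimate_pct` (contactless),
#' `reference_pct` (device).
#'
#' @return data frame with 30 rows.
#' @export
daily_observations <- function() {
  utils::read.csv(system.file("extdata", "daily_observations.csv",
                              package = "spo2cam"))
}

#' Packaged comparison readings: device vs. two red/blue formulas
#'
#' Six paired readings comparing the reference device against an earlier
#' red/blue additive calibration formula (`SpO2 = 97.61 + 0.42 * R`, which
#' cannot output below 97) and against this pipeline's subtractive one.
#' Columns: `reference_pct`, `comparison_pct`, `this_method_pct`.
#'
#' @return data frame with 6 rows.
#' @export
method_comparison <- function() {
  utils::read.csv(system.file("extdata", "method_comparison.csv",
                              package = "spo2cam"))
}
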