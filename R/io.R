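# Flat-file plumbing: CSV schemas for channel series and paired readings,
# JSON for calibration models and session reports. All round trips are
# lossless at full numeric precision.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_classed("spo2_schema_error", "%s is missing column '%s'",
                 what, missing[1])
  invisible(df)
}

require_numeric <- function(df, cols, what) {
  for (col in cols) {
    v <- df[[col]]
    bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
    if (anyNA(suppressWarnings(as.numeric(v))) && length(bad))
      stop_classed("spo2_schema_error",
                   "%s: non-numeric value in column '%s' at row %d",
                   what, col, bad[1])
    df[[col]] <- as.numeric(v)
  }
  df
}

#' Write a red/blue series pair to CSV
#'
#' Schema: `frame_index` (0-based), `time_s`, `red_bpp`, `blue_bpp`,
#' `filtered` (logical flag).
#'
#' @param red,blue aligned [channel_series()] (or `filtered_series`).
#' @param path output file.
#' @param filtered flag recorded in the `filtered` column.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(red, blue, path, filtered = FALSE) {
  n <- red$n_samples
  if (blue$n_samples != n || blue$fps != red$fps)
    stop_classed("spo2_parameter_error", "series must be aligned")
  fmt <- function(x) trimws(formatC(x, digits = 17, format = "g"))
  df <- data.frame(frame_index = seq_len(n) - 1L,
                   time_s = fmt((seq_len(n) - 1L) / red$fps),
                   red_bpp = fmt(red$values), blue_bpp = fmt(blue$values),
                   filtered = filtered)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a red/blue series pair from CSV
#'
#' The frame rate is recovered from the `time_s` column spacing;
#' `fps_fallback` is used when timing is absent or degenerate.
#'
#' @param path CSV written by [write_series_csv()] (or matching its schema).
#' @param fps_fallback frame rate assumed when `time_s` is unusable.
#' @return list with `red` and `blue` [channel_series()].
#' @export
read_series_csv <- function(path, fps_fallback = 30) {
  df <- utils::read.csv(path)
  require_columns(df, c("frame_index", "red_bpp", "blue_bpp"), "series CSV")
  df <- require_numeric(df, intersect(c("time_s", "red_bpp", "blue_bpp"),
                                      names(df)), "series CSV")
  fps <- fps_fallback
  if ("time_s" %in% names(df) && nrow(df) > 1L) {
    dt <- stats::median(diff(df$time_s))
    if (is.finite(dt) && dt > 0) fps <- 1 / dt
  }
  list(red = channel_series(df$red_bpp, fps, "red"),
       blue = channel_series(df$blue_bpp, fps, "blue"))
}

#' Read paired readings (estimate vs. reference) from CSV
#'
#' Schema: `estimate_pct`, `reference_pct`, plus optional `subject` / `day`
#' label columns.
#'
#' @param path CSV file.
#' @return a [paired_readings()].
#' @export
read_pairs_csv <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("estimate_pct", "reference_pct"), "pairs CSV")
  df <- require_numeric(df, c("estimate_pct", "reference_pct"), "pairs CSV")
  labels <- df[intersect(c("subject", "day", "tester"), names(df))]
  paired_readings(df$estimate_pct, df$reference_pct,
                  if (ncol(labels)) labels else NULL)
}

#' Read calibration pairs (ratio vs. reference SpO2) from CSV
#'
#' Schema: `r`, `spo2`.
#'
#' @param path CSV file.
#' @return data frame with numeric `r` and `spo2`.
#' @export
read_calibration_pairs_csv <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("r", "spo2"), "calibration pairs CSV")
  require_numeric(df, c("r", "spo2"), "calibration pairs CSV")
}

#' Write / read a calibration model as JSON
#'
#' @param model a [calibration_model()].
#' @param path JSON file.
#' @return `path` (write) or a [calibration_model()] (read).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(list(a = model$a, b = model$b, mode = model$mode),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("a", "b", "mode"))
    if (is.null(obj[[f]]))
      stop_classed("spo2_schema_error", "model JSON is missing field '%s'", f)
  calibration_model(obj$a, obj$b, obj$mode)
}

#' Write a session report (with full config provenance) as JSON
#'
#' @param report an `spo2_report` from [estimate_stream()] or
#'   [run_pipeline()].
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

report_to_list <- function(report) {
  list(summary = report$summary,
       triage = report$triage$label,
       n_windows = report$n_windows,
       n_rejected = report$n_rejected,
       windows = report$windows,
       config = list(model = list(a = report$model$a, b = report$model$b,
                                  mode = report$model$mode),
                     band = unclass(report$band),
                     window = report$window, hop = report$hop,
                     fps = report$fps,
                     seed = report$seed,
                     version = as.character(utils::packageVersion("spo2cam"))))
}
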