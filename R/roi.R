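# Forehead region-of-interest masking and channel-mean extraction: turns a
# frame sequence plus landmarks into the red/blue rPPG time series.

#' Construct a channel time series
#'
#' Per-frame mean intensity of one color channel over the forehead ROI, in
#' bits per pixel (bpp). `NA` marks frames with no valid ROI.
#'
#' @param values numeric vector in \[0, 255\] (NA allowed for gap frames).
#' @param fps sampling rate in frames per second, > 0.
#' @param channel `"red"` or `"blue"`.
#' @return object of class `channel_series`.
#' @export
channel_series <- function(values, fps, channel = c("red", "blue")) {
  channel <- match.arg(channel)
  if (!is.numeric(values) || length(values) == 0L)
    stop("values must be a non-empty numeric vector", call. = FALSE)
  ok <- is.na(values) | (values >= 0 & values <= 255)
  if (!all(ok))
    stop("channel values must lie in [0, 255] bpp", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  structure(list(values = as.numeric(values), fps = fps, channel = channel,
                 n_samples = length(values)),
            class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s, %d samples @ %.6g fps, mean %.2f bpp\n",
              x$channel, x$n_samples, x$fps, mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Rasterize the forehead polygon of a landmark set
#'
#' The mask is the filled convex hull of the 13 forehead points, clipped to
#' the frame. A pixel belongs to the mask when its center lies inside the
#' hull (half-open rasterization: an axis-aligned w x h rectangle covers
#' exactly w * h pixels).
#'
#' @param landmarks a [landmark_set()] (coordinates 0-based, (x, y) =
#'   (column, row)).
#' @param frame_dims `c(height, width)` of the frame in pixels.
#' @return object of class `roi_mask`: logical `height x width` matrix
#'   `mask`, integer `bbox` (`c(row0, row1, col0, col1)`, 1-based), and
#'   `pixel_count`.
#' @export
forehead_roi <- function(landmarks, frame_dims) {
  pts <- forehead_points(landmarks)
  h <- as.integer(frame_dims[1]); w <- as.integer(frame_dims[2])
  hull_idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[hull_idx, , drop = FALSE]
  if (nrow(hull) < 3L || polygon_area(hull) == 0)
    stop_classed("spo2_degenerate_roi",
                 "forehead landmarks are collinear or coincident: degenerate ROI")

  cmin <- max(1L, floor(min(hull[, 1])) + 1L)
  cmax <- min(w, ceiling(max(hull[, 1])))
  rmin <- max(1L, floor(min(hull[, 2])) + 1L)
  rmax <- min(h, ceiling(max(hull[, 2])))
  mask <- matrix(FALSE, h, w)
  if (cmin <= cmax && rmin <= rmax) {
    for (r in rmin:rmax) {
      py <- r - 0.5  # pixel-center y in the 0-based continuous frame
      for (cc in cmin:cmax) {
        mask[r, cc] <- point_in_polygon(cc - 0.5, py, hull)
      }
    }
  }
  n <- sum(mask)
  if (n == 0L)
    stop_classed("spo2_degenerate_roi",
                 "forehead polygon lies entirely outside the frame")
  idx <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask,
                 bbox = c(min(idx[, 1]), max(idx[, 1]),
                          min(idx[, 2]), max(idx[, 2])),
                 pixel_count = n),
            class = "roi_mask")
}

# Shoelace area of a polygon given as an n x 2 matrix.
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(n, seq_len(n - 1L))
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Even-odd ray-casting point-in-polygon test (half-open on shared edges).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Extract red and blue ROI-mean series from a frame sequence
#'
#' For every frame, the value of a channel is the arithmetic mean of that
#' channel's intensities over the mask pixels. The declared channel order of
#' the sequence is resolved, so RGB and BGR sources give identical output.
#' Frames whose mask is missing (a long detection gap) yield `NA` samples.
#'
#' @param frames a [frame_sequence()].
#' @param masks a single [forehead_roi()] mask applied to all frames, or a
#'   list with one mask (or [no_face()]) per frame.
#' @return list with elements `red` and `blue`, each a [channel_series()].
#' @export
extract_channel_series <- function(frames, masks) {
  stopifnot(inherits(frames, "frame_sequence"))
  n <- length(frames$frames)
  if (inherits(masks, "roi_mask")) masks <- rep(list(masks), n)
  if (length(masks) != n)
    stop("need one ROI mask per frame (or a single static mask)", call. = FALSE)
  ri <- channel_index("red", frames$channel_order)
  bi <- channel_index("blue", frames$channel_order)
  red <- numeric(n); blue <- numeric(n)
  for (i in seq_len(n)) {
    m <- masks[[i]]
    if (!inherits(m, "roi_mask") || m$pixel_count == 0L) {
      red[i] <- NA_real_; blue[i] <- NA_real_
      next
    }
    f <- frames$frames[[i]]
    red[i] <- mean(f[, , ri][m$mask])
    blue[i] <- mean(f[, , bi][m$mask])
  }
  list(red = channel_series(red, frames$fps, "red"),
       blue = channel_series(blue, frames$fps, "blue"))
}

# Classed condition helper shared across modules.
stop_classed <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
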