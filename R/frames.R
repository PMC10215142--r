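# Frame-sequence and landmark containers: the capture contract between a
# video source (camera backend, file reader, or the synthetic renderer) and
# the signal-extraction stages.

#' Construct a frame sequence
#'
#' An ordered list of H x W x 3 intensity arrays with a known frame rate.
#' The channel order of the source is recorded explicitly and resolved to
#' the canonical R, G, B order on access, so BGR sources (common in camera
#' libraries) extract identical series.
#'
#' @param frames list of numeric H x W x 3 arrays, all the same dimensions,
#'   values in \[0, 255\].
#' @param fps frames per second, > 0.
#' @param channel_order `"RGB"` (default) or `"BGR"`.
#' @param timestamps optional numeric vector of frame times in seconds.
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, channel_order = c("RGB", "BGR"),
                           timestamps = NULL) {
  channel_order <- match.arg(channel_order)
  if (!is.list(frames) || length(frames) == 0L)
    stop("frames must be a non-empty list of H x W x 3 arrays", call. = FALSE)
  dims <- dim(frames[[1]])
  if (length(dims) != 3L || dims[3] != 3L)
    stop("each frame must be an H x W x 3 array", call. = FALSE)
  same <- vapply(frames, function(f) identical(dim(f), dims), logical(1))
  if (!all(same))
    stop("all frames must share the same dimensions", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  if (!is.null(timestamps) && length(timestamps) != length(frames))
    stop("timestamps must have one entry per frame", call. = FALSE)
  structure(list(frames = frames, fps = fps, channel_order = channel_order,
                 timestamps = timestamps, dims = dims),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.6g fps, order %s\n",
              length(x$frames), x$dims[1], x$dims[2], x$fps, x$channel_order))
  invisible(x)
}

# Index of a named channel ("red"/"green"/"blue") given the declared order.
channel_index <- function(channel, channel_order) {
  canonical <- c(red = 1L, green = 2L, blue = 3L)
  i <- canonical[[channel]]
  if (channel_order == "BGR") i <- 4L - i
  i
}

#' Construct a facial landmark set
#'
#' 81 (x, y) pixel coordinates: the classic 68 facial points plus 13
#' forehead points. Coordinates are 0-based with (x, y) = (column, row) and
#' the origin at the top-left. Points are stored at 0-based indices 0-80;
#' the forehead block occupies indices 68-80 (rows 69-81 of the matrix).
#'
#' @param points numeric 81 x 2 matrix of (x, y) coordinates.
#' @param source label of the producing detector, e.g. `"synthetic"`.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points, source = "unknown") {
  points <- as.matrix(points)
  if (nrow(points) != 81L || ncol(points) != 2L)
    stop("a full-face landmark set has exactly 81 (x, y) points", call. = FALSE)
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  structure(list(points = points, source = source), class = "landmark_set")
}

#' Forehead points of a landmark set
#'
#' @param landmarks a `landmark_set`.
#' @return 13 x 2 matrix of (x, y) coordinates (0-based indices 68-80).
#' @export
forehead_points <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  landmarks$points[69:81, , drop = FALSE]
}

#' A no-face detection result
#'
#' Returned (never thrown) by landmark backends when a frame contains no
#' detectable face, so a dropped frame does not kill a stream.
#' @return object of class `no_face`.
#' @export
no_face <- function() structure(list(no_face = TRUE), class = "no_face")

#' @rdname no_face
#' @param x object to test.
#' @export
is_no_face <- function(x) inherits(x, "no_face")

# Registry of pluggable landmark backends. A backend is
# function(frame) -> landmark_set | no_face().
.landmark_backends <- new.env(parent = emptyenv())

#' Register a landmark-detection backend
#'
#' Landmarking is a pluggable interface: any detector (an external
#' HOG+SVM face model, a neural landmarker, or a synthetic fixture
#' provider) can be registered under a name. The built-in `"synthetic"`
#' backend returns landmarks embedded in the frame's `"landmarks"`
#' attribute, as produced by [synth_frames()], and a no-face result when
#' the attribute is absent.
#'
#' @param name backend name.
#' @param fn `function(frame)` returning a [landmark_set()] or [no_face()].
#' @export
register_landmark_backend <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .landmark_backends)
  invisible(name)
}

#' Detect facial landmarks on one frame
#'
#' @param frame an H x W x 3 array.
#' @param backend backend name previously registered, or a function.
#' @return a `landmark_set`, or [no_face()] if the frame has no face.
#' @export
detect_landmarks <- function(frame, backend = "synthetic") {
  fn <- if (is.function(backend)) backend
        else if (exists(backend, envir = .landmark_backends))
          get(backend, envir = .landmark_backends)
        else stop(sprintf("no landmark backend registered under '%s'", backend),
                  call. = FALSE)
  res <- fn(frame)
  if (!inherits(res, "landmark_set") && !is_no_face(res))
    stop("backend must return a landmark_set or no_face()", call. = FALSE)
  res
}

#' Detect landmarks over a sequence, filling short gaps
#'
#' Frames on which detection fails inherit the last valid landmark set for
#' up to `max_gap` frames (default: one second's worth), on the assumption
#' of a still subject. Longer gaps are left as no-face results and the
#' samples they cover are treated as invalid downstream.
#'
#' @param frames a `frame_sequence`.
#' @param backend as in [detect_landmarks()].
#' @param max_gap maximum carried-forward frames; default `ceiling(fps)`.
#' @return list with one `landmark_set` or `no_face` per frame.
#' @export
detect_landmarks_sequence <- function(frames, backend = "synthetic",
                                      max_gap = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (is.null(max_gap)) max_gap <- ceiling(frames$fps)
  out <- vector("list", length(frames$frames))
  last <- NULL
  gap <- 0L
  for (i in seq_along(frames$frames)) {
    res <- detect_landmarks(frames$frames[[i]], backend)
    if (is_no_face(res)) {
      gap <- gap + 1L
      out[[i]] <- if (!is.null(last) && gap <= max_gap) last else no_face()
    } else {
      gap <- 0L
      last <- res
      out[[i]] <- res
    }
  }
  out
}

# Default synthetic backend: landmarks travel with the frame.
.landmark_backends$synthetic <- function(frame) {
  lm <- attr(frame, "landmarks")
  if (is.null(lm)) return(no_face())
  if (inherits(lm, "landmark_set")) lm else landmark_set(lm, "synthetic")
}
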