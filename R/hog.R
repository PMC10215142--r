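# Histogram-of-oriented-gradients descriptor: the feature primitive behind
# landmark-based frontal-face detectors. Gradients are simple central
# differences, orientations are unsigned (folded onto [0, 180)), and block
# normalization removes global brightness scale.

HOG_BIN_CENTERS <- seq(0, 160, by = 20)
HOG_N_BINS <- 9L
HOG_BIN_WIDTH <- 20

#' Validate a grayscale image matrix
#'
#' @param image numeric matrix, values in \[0, 255\], at least 3 x 3.
#' @return the matrix, invisibly, after validation.
#' @keywords internal
validate_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3 x 3 for gradient computation", call. = FALSE)
  if (!all(is.finite(image)))
    stop("image contains non-finite values", call. = FALSE)
  if (min(image) < 0 || max(image) > 255)
    stop("image values must lie in [0, 255]", call. = FALSE)
  invisible(image)
}

#' Central-difference image gradients
#'
#' Horizontal gradient `gx(r, c) = I(r, c + 1) - I(r, c - 1)` and vertical
#' gradient `gy(r, c) = I(r - 1, c) - I(r + 1, c)` at every interior pixel.
#' Border pixels, where the central difference is undefined, are set to zero.
#'
#' @param image numeric matrix (rows x columns), values in \[0, 255\].
#' @return an object of class `gradient_field`: list with matrices `gx`,
#'   `gy`, `magnitude` (`sqrt(gx^2 + gy^2)`) and `angle` (unsigned
#'   orientation in degrees, in \[0, 180)).
#' @examples
#' g <- compute_gradients(matrix(rep(0:9, each = 10) * 10, nrow = 10))
#' range(g$gy[2:9, 2:9])
#' @export
compute_gradients <- function(image) {
  validate_gray_image(image)
  h <- nrow(image); w <- ncol(image)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- image[, 3:w] - image[, 1:(w - 2)]
  gy[2:(h - 1), ] <- image[1:(h - 2), ] - image[3:h, ]
  magnitude <- sqrt(gx^2 + gy^2)
  angle <- unsigned_angle(gx, gy)
  structure(list(gx = gx, gy = gy, magnitude = magnitude, angle = angle),
            class = "gradient_field")
}

# atan2 folded onto [0, 180); zero gradient maps to 0 degrees.
unsigned_angle <- function(gx, gy) {
  a <- atan2(gy, gx) * 180 / pi
  a <- a %% 180
  a[gx == 0 & gy == 0] <- 0
  a
}

#' Polar form of a single gradient vector
#'
#' Magnitude is the Euclidean norm; the angle is the unsigned orientation
#' `atan2(gy, gx) mod 180` in degrees, so opposite directions share one
#' orientation. A zero vector has magnitude 0 and angle 0; a vertical
#' gradient (`gx = 0`, `gy != 0`) has angle 90.
#'
#' @param gx,gy finite gradient components.
#' @return list with `magnitude` and `angle` (degrees in \[0, 180)).
#' @examples
#' gradient_polar(3, 4)  # magnitude 5, angle ~53.13
#' @export
gradient_polar <- function(gx, gy) {
  stopifnot(is.finite(gx), is.finite(gy))
  list(magnitude = sqrt(gx^2 + gy^2), angle = unsigned_angle(gx, gy))
}

#' Orientation histogram of one cell
#'
#' Accumulates gradient magnitudes of the pixels in a square cell into nine
#' orientation bins centered at 0, 20, ..., 160 degrees. Each magnitude is
#' split linearly between the two nearest bin centers, with circular
#' wrap-around between 160 and 0 (an angle of 170 contributes half to each).
#'
#' @param field a `gradient_field`.
#' @param cell_origin `(row, col)` of the cell's top-left pixel, 1-based.
#' @param cell_size side length of the cell in pixels.
#' @return numeric vector of 9 bin totals; attributes `cell_origin`,
#'   `cell_size`.
#' @export
cell_histogram <- function(field, cell_origin, cell_size = 8L) {
  stopifnot(inherits(field, "gradient_field"), length(cell_origin) == 2L)
  r0 <- cell_origin[[1]]; c0 <- cell_origin[[2]]
  h <- nrow(field$magnitude); w <- ncol(field$magnitude)
  if (r0 < 1L || c0 < 1L || r0 + cell_size - 1L > h || c0 + cell_size - 1L > w)
    stop("cell exceeds gradient field bounds", call. = FALSE)
  rows <- r0:(r0 + cell_size - 1L)
  cols <- c0:(c0 + cell_size - 1L)
  mag <- field$magnitude[rows, cols]
  ang <- field$angle[rows, cols]

  lower <- floor(ang / HOG_BIN_WIDTH)
  frac <- ang / HOG_BIN_WIDTH - lower
  lower <- as.integer(lower %% HOG_N_BINS)
  upper <- as.integer((lower + 1L) %% HOG_N_BINS)
  bins <- numeric(HOG_N_BINS)
  for (i in seq_along(mag)) {
    bins[lower[i] + 1L] <- bins[lower[i] + 1L] + mag[i] * (1 - frac[i])
    bins[upper[i] + 1L] <- bins[upper[i] + 1L] + mag[i] * frac[i]
  }
  structure(bins, cell_origin = c(r0, c0), cell_size = cell_size)
}

#' L2-normalized descriptor of a 2 x 2 block of cells
#'
#' Concatenates the four 9-bin cell histograms into a 36-vector and divides
#' by its Euclidean norm (with a small epsilon guarding division). An
#' all-zero block stays all-zero. Normalization makes the descriptor
#' invariant to a global intensity scale, which is its purpose: gradient
#' magnitudes grow with image brightness, orientations do not.
#'
#' @param cells list of exactly 4 nine-bin histograms (top-left, top-right,
#'   bottom-left, bottom-right).
#' @param eps regularizer added to the norm.
#' @return numeric vector of length 36 with Euclidean norm <= 1.
#' @export
block_normalize <- function(cells, eps = 1e-12) {
  if (length(cells) != 4L || !all(vapply(cells, length, 1L) == HOG_N_BINS))
    stop("a block is exactly 4 cells of 9 bins each", call. = FALSE)
  v <- as.numeric(unlist(cells, use.names = FALSE))
  nrm <- sqrt(sum(v^2) + eps^2)
  if (sum(v^2) == 0) return(numeric(36L))
  v / nrm
}

#' Full HOG descriptor of an image
#'
#' Tiles the image into `cell_size` x `cell_size` cells, forms 2 x 2-cell
#' blocks sliding by one cell, normalizes each block and concatenates the
#' 36-vectors in row-major block order. For the canonical 128 x 64 detection
#' window with 8-pixel cells this yields 15 x 7 blocks, a 3780-long vector.
#'
#' Color input (an H x W x 3 array) is reduced per pixel to the channel with
#' the largest gradient magnitude, whose orientation is kept.
#'
#' @param image numeric matrix, or H x W x 3 array for the max-channel path.
#' @param cell_size pixels per cell side (default 8).
#' @param gamma optional gamma-correction exponent applied to `image / 255`
#'   before gradients (e.g. 0.5); `NULL` (default) disables it.
#' @return numeric descriptor vector, length
#'   `(rows/cell - 1) * (cols/cell - 1) * 36`.
#' @examples
#' d <- hog_descriptor(matrix(runif(64 * 128, 0, 255), nrow = 128, ncol = 64))
#' length(d)  # 3780
#' @export
hog_descriptor <- function(image, cell_size = 8L, gamma = NULL) {
  if (is.array(image) && length(dim(image)) == 3L) {
    field <- max_channel_gradients(image, gamma)
    h <- dim(image)[1]; w <- dim(image)[2]
  } else {
    if (!is.null(gamma)) {
      validate_gray_image(image)
      image <- (image / 255)^gamma * 255
    }
    field <- compute_gradients(image)
    h <- nrow(image); w <- ncol(image)
  }
  if (h %% cell_size != 0L || w %% cell_size != 0L)
    stop("image dimensions must be multiples of cell_size", call. = FALSE)
  cy <- h %/% cell_size; cx <- w %/% cell_size
  if (cy < 2L || cx < 2L)
    stop("image too small: need at least 2 x 2 cells", call. = FALSE)

  hists <- vector("list", cy * cx)
  for (i in seq_len(cy)) {
    for (j in seq_len(cx)) {
      hists[[(i - 1L) * cx + j]] <- cell_histogram(
        field, c((i - 1L) * cell_size + 1L, (j - 1L) * cell_size + 1L),
        cell_size)
    }
  }
  cell_at <- function(i, j) hists[[(i - 1L) * cx + j]]
  out <- vector("list", (cy - 1L) * (cx - 1L))
  k <- 1L
  for (i in seq_len(cy - 1L)) {
    for (j in seq_len(cx - 1L)) {
      out[[k]] <- block_normalize(list(cell_at(i, j), cell_at(i, j + 1L),
                                       cell_at(i + 1L, j), cell_at(i + 1L, j + 1L)))
      k <- k + 1L
    }
  }
  unlist(out, use.names = FALSE)
}

# Per-pixel selection of the color channel with the strongest gradient.
max_channel_gradients <- function(image, gamma = NULL) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  fields <- lapply(1:3, function(ch) {
    plane <- image[, , ch]
    if (!is.null(gamma)) plane <- (plane / 255)^gamma * 255
    compute_gradients(plane)
  })
  mags <- vapply(fields, function(f) f$magnitude,
                 matrix(0, dim(image)[1], dim(image)[2]))
  pick <- apply(mags, c(1, 2), which.max)
  take <- function(what) {
    out <- fields[[1]][[what]]
    for (ch in 2:3) {
      sel <- pick == ch
      out[sel] <- fields[[ch]][[what]][sel]
    }
    out
  }
  structure(list(gx = take("gx"), gy = take("gy"),
                 magnitude = take("magnitude"), angle = take("angle")),
            class = "gradient_field")
}
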