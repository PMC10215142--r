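# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles with naive loops, so they share no code
# path with the implementation they check.

# Naive per-pixel HOG: central differences, unsigned atan2 orientation,
# per-pixel linear bin split with wrap, L2 block normalization.
oracle_hog <- function(image, cell_size = 8L) {
  h <- nrow(image); w <- ncol(image)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (r in 2:(h - 1)) for (cc in 2:(w - 1)) {
    gx[r, cc] <- image[r, cc + 1] - image[r, cc - 1]
    gy[r, cc] <- image[r - 1, cc] - image[r + 1, cc]
  }
  # borders: columns 1 and w for gx, rows 1 and h for gy stay 0, but the
  # orthogonal gradient is still defined there
  for (r in 2:(h - 1)) {
    gy[r, 1] <- image[r - 1, 1] - image[r + 1, 1]
    gy[r, w] <- image[r - 1, w] - image[r + 1, w]
  }
  for (cc in 2:(w - 1)) {
    gx[1, cc] <- image[1, cc + 1] - image[1, cc - 1]
    gx[h, cc] <- image[h, cc + 1] - image[h, cc - 1]
  }
  cy <- h %/% cell_size; cx <- w %/% cell_size
  hists <- array(0, dim = c(cy, cx, 9))
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    m <- sqrt(gx[r, cc]^2 + gy[r, cc]^2)
    if (m == 0) next
    a <- (atan2(gy[r, cc], gx[r, cc]) * 180 / pi) %% 180
    lo <- floor(a / 20); fr <- a / 20 - lo
    ci <- (r - 1) %/% cell_size + 1; cj <- (cc - 1) %/% cell_size + 1
    hists[ci, cj, (lo %% 9) + 1] <- hists[ci, cj, (lo %% 9) + 1] + m * (1 - fr)
    hists[ci, cj, ((lo + 1) %% 9) + 1] <- hists[ci, cj, ((lo + 1) %% 9) + 1] + m * fr
  }
  out <- numeric(0)
  for (i in seq_len(cy - 1)) for (j in seq_len(cx - 1)) {
    v <- c(hists[i, j, ], hists[i, j + 1, ], hists[i + 1, j, ], hists[i + 1, j + 1, ])
    nrm <- sqrt(sum(v^2) + 1e-24)
    out <- c(out, if (sum(v^2) == 0) v else v / nrm)
  }
  out
}

# Two-pass population sd and mean by explicit summation.
oracle_window <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v
  m <- m / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  list(sd = sqrt(ss / n), mean = m)
}

# Brute-force mean of one channel over a logical mask.
oracle_masked_mean <- function(plane, mask) {
  s <- 0; n <- 0L
  for (r in seq_len(nrow(plane))) for (cc in seq_len(ncol(plane))) {
    if (mask[r, cc]) { s <- s + plane[r, cc]; n <- n + 1L }
  }
  s / n
}

# Brute-force count of pixel centers inside a convex polygon (0-based
# continuous coordinates), by winding-free even-odd ray casting written
# independently of the package's rasterizer.
oracle_pixels_inside <- function(poly, h, w) {
  count <- 0L
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    px <- cc - 0.5; py <- r - 0.5
    inside <- FALSE
    n <- nrow(poly); j <- n
    for (i in seq_len(n)) {
      yi <- poly[i, 2]; yj <- poly[j, 2]
      if ((yi > py) != (yj > py)) {
        xi <- poly[i, 1]; xj <- poly[j, 1]
        if (px < xi + (py - yi) * (xj - xi) / (yj - yi)) inside <- !inside
      }
      j <- i
    }
    if (inside) count <- count + 1L
  }
  count
}

# A tiny uniform random image in [0, 255].
random_image <- function(h, w) matrix(stats::runif(h * w, 0, 255), h, w)

# Frame with a constant value per channel and embedded fixture landmarks.
constant_frame <- function(h, w, rgb, landmarks = NULL) {
  f <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) f[, , ch] <- rgb[ch]
  if (!is.null(landmarks)) attr(f, "landmarks") <- landmarks
  f
}

# Landmark set whose forehead hull is an axis-aligned rectangle.
rect_landmarks <- function(x0, y0, w, h) {
  fore <- rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h),
                c(x0 + w / 2, y0), c(x0 + w / 2, y0 + h),
                c(x0, y0 + h / 2), c(x0 + w, y0 + h / 2),
                c(x0 + w / 4, y0), c(x0 + 3 * w / 4, y0),
                c(x0 + w / 4, y0 + h), c(x0 + 3 * w / 4, y0 + h),
                c(x0 + w / 2, y0 + h / 2))
  face <- cbind(rep(x0, 68), rep(y0, 68))
  landmark_set(rbind(face, fore), source = "synthetic")
}
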