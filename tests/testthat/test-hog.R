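test_that("central-difference gradients follow the definition", {
  # constant image: zero gradient everywhere
  g <- compute_gradients(matrix(128, 8, 8))
  expect_true(all(g$gx == 0) && all(g$gy == 0) && all(g$magnitude == 0))

  # a pixel with neighbors 10 (right) and 4 (left) has gx = 6
  im <- matrix(0, 5, 5)
  im[3, 4] <- 10; im[3, 2] <- 4
  expect_equal(compute_gradients(im)$gx[3, 3], 6)

  # vertical ramp I(r, c) = r: gy = (r-1) - (r+1) = -2 at interior pixels
  ramp <- matrix(rep(1:10), nrow = 10, ncol = 6)
  g <- compute_gradients(ramp)
  expect_true(all(g$gy[2:9, ] == -2))
  expect_true(all(g$gx[, 2:5] == 0))

  expect_error(compute_gradients(matrix(0, 2, 5)), "3 x 3")
})

test_that("polar form folds orientations onto [0, 180)", {
  p <- gradient_polar(3, 4)
  expect_equal(p$magnitude, 5)
  expect_equal(p$angle, atan2(4, 3) * 180 / pi, tolerance = 1e-12)

  # sign-case table for the unsigned-orientation fold
  cases <- list(list(1, 0, 0), list(0, 1, 90), list(0, -1, 90),
                list(-1, 0, 0), list(1, 1, 45), list(-1, 1, 135),
                list(-1, -1, 45), list(1, -1, 135), list(0, 0, 0))
  for (cs in cases) {
    p <- gradient_polar(cs[[1]], cs[[2]])
    expect_equal(p$angle, cs[[3]], tolerance = 1e-12,
                 label = sprintf("angle(%g, %g)", cs[[1]], cs[[2]]))
  }
  expect_equal(gradient_polar(-1, 1)$magnitude, sqrt(2))
})

test_that("cell histogram splits magnitude linearly with wrap-around", {
  mk_field <- function(angle, mag, n = 2) {
    structure(list(gx = matrix(1, n, n), gy = matrix(0, n, n),
                   magnitude = matrix(mag, n, n),
                   angle = matrix(angle, n, n)),
              class = "gradient_field")
  }
  # on-center angles land in one bin
  bins <- cell_histogram(mk_field(40, 2.5), c(1, 1), 2)
  expect_equal(as.numeric(bins), c(0, 0, 10, 0, 0, 0, 0, 0, 0))

  # 10 degrees is midway between the 0 and 20 centers
  f <- mk_field(10, 4, 1)
  bins <- cell_histogram(f, c(1, 1), 1)
  expect_equal(as.numeric(bins)[1:2], c(2, 2))

  # 170 degrees wraps between the 160 and 0 centers
  f <- mk_field(170, 2, 1)
  bins <- cell_histogram(f, c(1, 1), 1)
  expect_equal(as.numeric(bins)[c(9, 1)], c(1, 1))

  expect_error(cell_histogram(mk_field(0, 1, 4), c(3, 3), 4), "bounds")
})

test_that("histogram conserves total gradient magnitude", {
  set.seed(11)
  for (i in 1:5) {
    im <- random_image(12, 12)
    g <- compute_gradients(im)
    bins <- cell_histogram(g, c(3, 3), 8)
    expect_equal(sum(bins), sum(g$magnitude[3:10, 3:10]), tolerance = 1e-9)
  }
})

test_that("block normalization is unit-norm, zero-safe and scale-free", {
  cells <- rep(list(c(1, rep(0, 8))), 4)
  v <- block_normalize(cells)
  expect_length(v, 36)
  expect_equal(v[v != 0], rep(0.5, 4))

  expect_equal(block_normalize(rep(list(numeric(9)), 4)), numeric(36))

  set.seed(7)
  base <- lapply(1:4, function(i) runif(9))
  ref <- block_normalize(base)
  for (k in c(2, 10, 100)) {
    scaled <- lapply(base, function(c) k * c)
    expect_equal(block_normalize(scaled), ref, tolerance = 1e-6)
  }
  expect_lte(sqrt(sum(ref^2)), 1 + 1e-9)
  expect_error(block_normalize(rep(list(numeric(9)), 3)), "4 cells")
})

test_that("full descriptor has the canonical layout and invariances", {
  set.seed(3)
  im <- random_image(128, 64)
  d <- hog_descriptor(im)
  expect_length(d, 15 * 7 * 36)

  expect_equal(hog_descriptor(matrix(77, 32, 32)), numeric(3 * 3 * 36))

  # brightness offset cancels in the differences: exact equality
  small <- random_image(16, 16) * 0.3
  expect_equal(hog_descriptor(small + 30, cell_size = 4),
               hog_descriptor(small + 80, cell_size = 4), tolerance = 1e-12)

  # global intensity scale is removed by block normalization
  expect_equal(hog_descriptor(small * 3, cell_size = 4),
               hog_descriptor(small, cell_size = 4), tolerance = 1e-6)

  expect_error(hog_descriptor(random_image(30, 30)), "multiples")
})

test_that("descriptor matches the brute-force oracle bin for bin", {
  set.seed(42)
  for (i in 1:4) {
    im <- random_image(16, 16)
    expect_equal(hog_descriptor(im, cell_size = 8), oracle_hog(im, 8),
                 tolerance = 1e-9)
  }
})

test_that("magnitude identity holds at every pixel", {
  set.seed(5)
  g <- compute_gradients(random_image(20, 20))
  expect_lt(max(abs(g$magnitude^2 - (g$gx^2 + g$gy^2))), 1e-9)
  expect_true(all(g$angle >= 0 & g$angle < 180))
})

test_that("color input picks the strongest channel per pixel", {
  arr <- array(0, dim = c(16, 16, 3))
  set.seed(9)
  arr[, , 2] <- random_image(16, 16)  # only green carries structure
  expect_equal(hog_descriptor(arr, cell_size = 8),
               hog_descriptor(arr[, , 2], cell_size = 8), tolerance = 1e-12)
})
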