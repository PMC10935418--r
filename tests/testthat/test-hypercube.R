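test_that("wavelength grid covers the half-open range at uniform step", {
  g <- wavelength_grid(400, 1000, 2)
  expect_length(g$centers, 300)
  expect_equal(g$centers[1], 400)
  expect_equal(g$centers[300], 998)
  expect_equal(unique(diff(g$centers)), 2)

  g1 <- wavelength_grid(400, 402, 2)
  expect_length(g1$centers, 1)
  expect_equal(g1$centers, 400)

  expect_error(wavelength_grid(400, 1000, 7), "not divisible")
  expect_error(wavelength_grid(1000, 400, 2), "exceed")
  expect_error(wavelength_grid(400, 1000, -2), "positive")
})

test_that("band_index snaps to the nearest center and rejects off-grid", {
  g <- wavelength_grid(400, 1000, 2)
  expect_equal(band_index(g, 400), 1)
  expect_equal(band_index(g, 801), 201) # nearest of 800/802
  expect_error(band_index(g, 1200), "not on the grid")
})

test_that("reflectance calibration matches (I_s - D)/(I_w - D) element-wise", {
  g <- tiny_grid()
  p <- length(g)
  raw <- hypercube(array(0.5, c(4, 5, p)), g, "raw")
  refs <- reference_frame(matrix(0.9, 5, p), matrix(0.1, 5, p))
  out <- calibrate_reflectance(raw, refs)
  expect_equal(out$kind, "reflectance")
  expect_true(all(abs(out$values - 0.5) < 1e-12))

  # perfect reflector: sample counts equal white counts
  raw_w <- hypercube(array(0.9, c(4, 5, p)), g, "raw")
  expect_true(all(calibrate_reflectance(raw_w, refs)$values == 1))

  # dark floor: sample counts equal dark counts
  raw_d <- hypercube(array(0.1, c(4, 5, p)), g, "raw")
  expect_true(all(calibrate_reflectance(raw_d, refs)$values == 0))
})

test_that("calibration is idempotent for unit white, zero dark", {
  g <- tiny_grid()
  set.seed(1)
  vals <- array(runif(4 * 5 * length(g)), c(4, 5, length(g)))
  raw <- hypercube(vals, g, "raw")
  refs <- reference_frame(matrix(1, 5, length(g)), matrix(0, 5, length(g)))
  expect_equal(calibrate_reflectance(raw, refs)$values, vals)
})

test_that("dead-pixel denominators are floored and output is clipped", {
  g <- wavelength_grid(400, 402, 2)
  raw <- hypercube(array(c(5, 0.5), c(2, 1, 1)), g, "raw")
  white <- matrix(1e-9, 1, 1) + 0 # near-dark white pixel
  dark <- matrix(0, 1, 1)
  refs <- reference_frame(white, dark, min_positive_frac = 0)
  out <- calibrate_reflectance(raw, refs, epsilon = 1e-6, clip_max = 2)
  expect_true(all(is.finite(out$values)))
  expect_true(all(out$values <= 2 & out$values >= 0))
})

test_that("calibration commutes with spatial cropping", {
  g <- tiny_grid()
  set.seed(2)
  p <- length(g)
  raw <- hypercube(array(runif(6 * 7 * p, 100, 900), c(6, 7, p)), g, "raw")
  refs <- reference_frame(matrix(runif(7 * p, 900, 1000), 7, p),
                          matrix(runif(7 * p, 0, 50), 7, p))
  lines <- 2:4
  pixels <- c(1, 3, 6)
  a <- crop_cube(calibrate_reflectance(raw, refs), lines, pixels)
  refs_c <- reference_frame(refs$white[pixels, ], refs$dark[pixels, ])
  b <- calibrate_reflectance(crop_cube(raw, lines, pixels), refs_c)
  expect_equal(a$values, b$values)
})

test_that("mismatched shapes and degenerate references are rejected", {
  g <- tiny_grid()
  p <- length(g)
  raw <- hypercube(array(1, c(4, 5, p)), g, "raw")
  refs_bad <- reference_frame(matrix(1, 4, p), matrix(0, 4, p))
  expect_error(calibrate_reflectance(raw, refs_bad), "shape")
  expect_error(reference_frame(matrix(0, 5, p), matrix(0, 5, p)),
               "all-zero white")
  expect_error(reference_frame(matrix(0.1, 5, p), matrix(0.5, 5, p)),
               "exceeds dark")
  refl <- hypercube(array(1, c(4, 5, p)), g, "reflectance")
  refs <- reference_frame(matrix(1, 5, p), matrix(0, 5, p))
  expect_error(calibrate_reflectance(refl, refs), "raw-kind")
})
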