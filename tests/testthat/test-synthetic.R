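test_that("the deterministic path reproduces the analytic template", {
  tpl <- clean_template()
  grid <- wavelength_grid()
  tab <- generate_spectra_dataset(n_fruits = 1, template = tpl,
                                  ssc_dist = ssc_distribution(), seed = 1)
  # both orientations identical and equal to the analytic curve
  expect_equal(tab$X[1, ], tab$X[2, ])
  expect_equal(unname(tab$X[1, ]),
               template_spectrum(tpl, grid, tab$ssc[1]), tolerance = 1e-12)
})

test_that("higher SSC deepens the 960 nm absorption", {
  tpl <- clean_template()
  grid <- wavelength_grid()
  b960 <- band_index(grid, 960)
  lo <- template_spectrum(tpl, grid, 8)[b960]
  hi <- template_spectrum(tpl, grid, 12)[b960]
  expect_lt(hi, lo)
  # and the noise-free spectrum stays within physical bounds
  for (s in c(7.4, 9.85, 12.5)) {
    sp <- template_spectrum(tpl, grid, s)
    expect_true(all(sp >= 0 & sp <= 1.2))
  }
})

test_that("drawn SSC follows the truncated harvest distribution", {
  tab <- generate_spectra_dataset(n_fruits = 324, seed = 19)
  per_fruit <- tab$ssc[!duplicated(tab$fruit_id)]
  expect_length(tab$ssc, 648)
  expect_length(per_fruit, 324)
  expect_true(all(per_fruit >= 7.40 & per_fruit <= 12.50))
  se <- sd(per_fruit) / sqrt(324)
  expect_lt(abs(mean(per_fruit) - 9.85), 3 * se)
  # orientation pairs share the fruit's SSC
  expect_equal(tab$ssc[seq(1, 647, by = 2)], tab$ssc[seq(2, 648, by = 2)])
})

test_that("cube generation, calibration and extraction form an identity", {
  tpl <- citrus_template(pigment_variability = 0, gain_sd = 0,
                         offset_sd = 0, noise_sd = 0.005)
  sc <- generate_cube(fruit_radius_px = 10, scene_dims = c(32, 32),
                      template = tpl, ssc = 10.2, seed = 3)
  refl <- calibrate_reflectance(sc$cube, sc$refs)
  mask <- segment_threshold(refl, band_nm = 800, threshold = 0.2)
  got <- unname(mean_spectrum(refl, mask))
  tol <- 2 * 0.005 / sqrt(sum(sc$mask))
  expect_true(all(abs(got - sc$spectrum) <= 4 * tol))
  expect_lt(sqrt(mean((got - sc$spectrum)^2)), 2 * tol)
  # background pixels all excluded at the default threshold
  expect_true(all(!mask$values[!sc$mask]))

  # unit white / zero dark: raw counts equal intended reflectance
  sc0 <- generate_cube(fruit_radius_px = 5, scene_dims = c(16, 16),
                       template = clean_template(), white_level = 1,
                       dark_level = 0, noise_sd = 0, seed = 4)
  inside <- which(sc0$mask, arr.ind = TRUE)[1, ]
  expect_equal(sc0$cube$values[inside[1], inside[2], ],
               sc0$spectrum, tolerance = 1e-12)
  expect_error(generate_cube(0), "radius")
  expect_error(generate_cube(40, scene_dims = c(20, 20)), "fit")
})

test_that("with noise and scatter off the whole front end is exact", {
  tpl <- clean_template()
  sc <- generate_cube(fruit_radius_px = 8, scene_dims = c(24, 24),
                      template = tpl, ssc = 9.0, noise_sd = 0)
  refl <- calibrate_reflectance(sc$cube, sc$refs)
  mask <- segment_threshold(refl, band_nm = 800, threshold = 0.2)
  got <- unname(mean_spectrum(refl, mask))
  expect_lt(max(abs(got - sc$spectrum)), 1e-6)
})

test_that("the planted signal is low rank: noise-free PLSR is exact", {
  tpl <- clean_template()
  tab <- generate_spectra_dataset(n_fruits = 40, template = tpl, seed = 5)
  m <- pls_fit(tab, n_factors = 3)
  rmsec <- sqrt(mean((tab$ssc - predict(m, tab))^2))
  expect_lte(m$n_factors, 3)
  expect_lt(rmsec, 1e-6)
})

test_that("outlier injection is reproducible and validated", {
  tab <- generate_spectra_dataset(n_fruits = 324, seed = 20)
  inj <- inject_outliers(tab, n_outliers = 17, seed = 6)
  expect_length(inj$planted, 17)
  expect_false(any(duplicated(inj$planted)))
  again <- inject_outliers(tab, n_outliers = 17, seed = 6)
  expect_identical(inj$planted, again$planted)
  expect_identical(inj$table$ssc, again$table$ssc)
  # shifted by the stated multiple of the noise-equivalent sd
  shift <- abs(inj$table$ssc - tab$ssc)[inj$planted]
  expect_equal(unname(shift),
               rep(5 * attr(tab, "ssc_noise_floor"), 17))
  expect_error(inject_outliers(tab, n_outliers = 100), "tenth")
  expect_error(inject_outliers(tab, shift_sd_multiples = 0), "zero shift")
})

test_that("spectra tables survive a CSV round trip", {
  tab <- generate_spectra_dataset(n_fruits = 5, seed = 21)
  path <- file.path(tempdir(), "spectra.csv")
  write_spectra_csv(tab, path)
  back <- read_spectra_csv(path)
  expect_equal(back$X, tab$X, tolerance = 1e-12)
  expect_equal(back$ssc, tab$ssc)
  expect_equal(back$wavelengths, tab$wavelengths)
})
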