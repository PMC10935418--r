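test_that("moving average matches hand-computed shrinking windows", {
  # 3-point window: gap 2 nm at 2 nm step, half-width reading
  expect_equal(moving_average(c(1, 2, 3, 4, 5), window_nm = 2, step_nm = 2),
               c(1.5, 2, 3, 4, 4.5))
  expect_equal(moving_average(rep(2.5, 20), window_nm = 6, step_nm = 2),
               rep(2.5, 20))
  # linear ramp: interior points unchanged under symmetric averaging
  ramp <- seq(0, 3.8, by = 0.2)
  sm <- moving_average(ramp, window_nm = 6, step_nm = 2)
  expect_equal(sm[4:17], ramp[4:17])
  expect_error(moving_average(1:3, window_nm = 20, step_nm = 2), "wider")
  # window must be a multiple of the step
  expect_error(moving_average(1:20, window_nm = 5, step_nm = 2),
               "multiple")
})

test_that("Savitzky-Golay first derivative is exact on low-order polynomials", {
  lam <- seq(400, 478, by = 2)
  expect_equal(sg_first_derivative(rep(1.3, 40), step_nm = 2), rep(0, 40))
  # linear ramp with slope 0.01 per nm
  expect_equal(sg_first_derivative(0.01 * lam, step_nm = 2),
               rep(0.01, 40), tolerance = 1e-10)
  # quadratic: analytic derivative 2a(lam - 440)
  x <- 1e-4 * (lam - 440)^2
  expect_equal(sg_first_derivative(x, step_nm = 2, poly_order = 2),
               2e-4 * (lam - 440), tolerance = 1e-10)
  expect_error(sg_first_derivative(c(1, 2), step_nm = 2), "too short")
})

test_that("normalizations rescale as defined and reject degenerate input", {
  expect_equal(normalize_spectrum(c(0.5, 1, 2), "max"), c(0.25, 0.5, 1))
  expect_equal(normalize_spectrum(c(1, 2, 3), "mean"), c(0.5, 1, 1.5))
  expect_equal(normalize_spectrum(c(2, 4, 6), "range"), c(0, 0.5, 1))
  expect_error(normalize_spectrum(c(0, 0), "max"), "maximum")
  expect_error(normalize_spectrum(c(1, -1), "mean"), "mean")
  expect_error(normalize_spectrum(c(2, 2), "range"), "no spread")
})

test_that("SNV standardizes with the n-1 deviation and is affine invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(8)
  x <- runif(30)
  expect_equal(snv(3.7 * x + 0.4), snv(x))
  out <- snv(x)
  expect_equal(mean(out), 0)
  expect_equal(sd(out), 1)
  expect_error(snv(rep(1, 5)), "constant")
})

test_that("MSC corrects affine scatter against its reference exactly", {
  set.seed(9)
  ref <- 0.3 + 0.4 * sin(seq(0, 3, length.out = 50))
  # spectrum equal to the reference is unchanged
  expect_equal(drop(msc(rbind(ref), reference = ref)$X), ref)
  # exact affine model is fully corrected
  expect_equal(drop(msc(rbind(2 * ref + 0.3), reference = ref)$X), ref)
  # random table: re-regressing corrected spectra on the reference
  # gives intercept 0, slope 1
  X <- t(replicate(12, (0.8 + runif(1) * 0.4) * ref + rnorm(1, 0, 0.05) +
                     rnorm(50, 0, 0.01)))
  fit <- msc(X)
  for (i in 1:12) {
    cf <- coef(lm(fit$X[i, ] ~ fit$reference))
    expect_equal(unname(cf[1]), 0, tolerance = 1e-8)
    expect_equal(unname(cf[2]), 1, tolerance = 1e-8)
  }
})

test_that("batch preprocessing equals row-wise application", {
  set.seed(10)
  X <- matrix(runif(6 * 40, 0.1, 0.9), 6, 40)
  for (m in c("moving_average", "sg_first_derivative", "norm_max",
              "norm_mean", "norm_range", "snv")) {
    pp <- fit_preprocessor(preprocessor(m), X)
    batch <- apply_preprocessor(pp, X)
    rows <- t(sapply(seq_len(6), function(i) {
      drop(apply_preprocessor(pp, X[i, , drop = FALSE]))
    }))
    expect_equal(unname(batch), unname(rows), info = m)
    expect_equal(dim(batch), dim(X), info = m)
  }
})

test_that("a fitted MSC reference is frozen for prediction rows", {
  set.seed(11)
  ref_shape <- 0.3 + 0.4 * sin(seq(0, 3, length.out = 40))
  Xcal <- t(replicate(8, ref_shape * runif(1, 0.8, 1.2) + rnorm(1, 0, 0.03)))
  pp <- fit_preprocessor(preprocessor("msc"), Xcal)
  expect_equal(pp$msc_reference, colMeans(Xcal))
  # gain/offset applied to a new spectrum is removed exactly under the
  # frozen reference
  xnew <- rbind(ref_shape)
  a <- apply_preprocessor(pp, xnew)
  b <- apply_preprocessor(pp, 1.7 * xnew + 0.2)
  expect_equal(a, b, tolerance = 1e-10)
})
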