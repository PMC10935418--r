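test_that("a single-column exact relation is recovered with one factor", {
  m <- pls_fit(matrix(c(1, 2, 3)), c(2, 4, 6), 1)
  expect_equal(unname(predict(m, matrix(c(1, 2, 3)))), c(2, 4, 6))
  expect_equal(unname(m$coefficients[, 1]), 2)
  expect_equal(unname(m$intercepts[1]), 0)
})

test_that("full-rank PLSR predictions coincide with least squares", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(15:30, 1)
    p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n, 0, 0.3)
    m <- pls_fit(X, y, n_factors = p)
    expect_equal(unname(predict(m, X)), ols_predictions(X, y),
                 tolerance = 1e-8)
  }
})

test_that("uninformative predictors give near-zero calibration R2", {
  r2 <- sapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(400 * 10), 400, 10)
    y <- rnorm(400)
    m <- pls_fit(X, y, n_factors = 1)
    evaluate_predictions(y, predict(m, X), "calibration")$R2
  })
  expect_true(median(r2) < 0.05)
  expect_true(max(r2) < 0.15)
})

test_that("prediction contracts hold: centroid, null model, band mismatch", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(40, 0, 0.1)
  m <- pls_fit(X, y, 4)
  expect_equal(unname(predict(m, matrix(m$x_mean, 1))), m$y_mean)
  expect_equal(unname(predict(m, X, n_factors = 0)), rep(m$y_mean, 40))
  expect_error(predict(m, X[, 1:3]), "bands")
  expect_error(predict(m, X, n_factors = 9), "holds")
})

test_that("score vectors are orthogonal and factorizations agree", {
  set.seed(13)
  X <- matrix(rnorm(50 * 20), 50, 20)
  y <- drop(X[, 1:3] %*% c(1, 2, -1)) + rnorm(50, 0, 0.2)
  m <- pls_fit(X, y, 8)
  G <- crossprod(m$x_scores)
  off <- max(abs(G[upper.tri(G)])) / max(diag(G))
  expect_lt(off, 1e-8)
  # prediction from the factorization path (scores on new data) equals
  # the collapsed-coefficient path
  Xc <- sweep(X, 2, m$x_mean)
  R <- m$weights %*% solve(crossprod(m$x_loadings, m$weights))
  scores <- Xc %*% R
  yhat_fact <- drop(scores %*% m$y_loadings) + m$y_mean
  expect_equal(yhat_fact, unname(predict(m, X)), tolerance = 1e-10)
})

test_that("centering makes predictions shift-invariant per band", {
  set.seed(14)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- drop(X %*% rnorm(5))
  Xn <- matrix(rnorm(10 * 5), 10, 5)
  m1 <- pls_fit(X, y, 3)
  shift <- c(5, -2, 0, 7, 1)
  m2 <- pls_fit(sweep(X, 2, shift, "+"), y, 3)
  expect_equal(predict(m1, Xn), predict(m2, sweep(Xn, 2, shift, "+")),
               tolerance = 1e-8)
})

test_that("cross-validation finds the exact rank of noiseless data", {
  set.seed(15)
  t_lat <- rnorm(30)
  X <- t_lat %*% t(rnorm(12)) # rank-1
  y <- 2 * t_lat + 5
  cv <- pls_cv(X, y, max_factors = 5)
  expect_equal(cv$optimal_factors, 1)
  expect_lt(cv$rmsecv[1], 1e-8)
  expect_error(pls_cv(X[1:2, ], y[1:2], 2), "at least 3")
})

test_that("k-fold cross-validation is reproducible under a fixed seed", {
  set.seed(16)
  X <- matrix(rnorm(60 * 15), 60, 15)
  y <- drop(X[, 1:2] %*% c(1, 1)) + rnorm(60, 0, 0.5)
  a <- pls_cv(X, y, 10, scheme = "kfold", k = 5, seed = 99)
  b <- pls_cv(X, y, 10, scheme = "kfold", k = 5, seed = 99)
  expect_identical(a$rmsecv, b$rmsecv)
  # and the kernel-downdated held-out fits match explicit refits
  loo <- pls_cv(X, y, 4, scheme = "loo")
  i <- 7
  m_i <- pls_fit(X[-i, ], y[-i], 4)
  expect_equal(loo$cv_predictions[i, 4],
               unname(predict(m_i, X[i, , drop = FALSE])),
               tolerance = 1e-8)
})

test_that("split sizes round half away from zero at a 7:3 ratio", {
  mk <- function(n) spectra_table(matrix(rnorm(n * 3), n, 3), rnorm(n), 1:3)
  s648 <- split_dataset(mk(648), 0.7, seed = 1)
  expect_equal(length(s648$calibration_idx), 454)
  expect_equal(length(s648$prediction_idx), 194)
  s631 <- split_dataset(mk(631), 0.7, seed = 1)
  expect_equal(length(s631$calibration_idx), 442)
  expect_equal(length(s631$prediction_idx), 189)
  s10 <- split_dataset(mk(10), 0.7, seed = 1)
  expect_equal(length(s10$calibration_idx), 7)
  # disjoint, exhaustive, reproducible
  expect_equal(sort(c(s648$calibration_idx, s648$prediction_idx)), 1:648)
  again <- split_dataset(mk(648), 0.7, seed = 1)
  expect_identical(again$calibration_idx, s648$calibration_idx)
  expect_error(split_dataset(mk(5), 0.05), "empty")
})

test_that("grouped splitting keeps orientation replicates together", {
  tb <- spectra_table(matrix(rnorm(40 * 3), 40, 3), rnorm(40), 1:3,
                      fruit_id = rep(1:20, each = 2),
                      orientation = rep(c("a", "b"), 20))
  sp <- split_dataset(tb, 0.7, seed = 3, group_by_fruit = TRUE)
  shared <- intersect(sp$calibration$fruit_id, sp$prediction$fruit_id)
  expect_length(shared, 0)
})

test_that("evaluation metrics match their definitions", {
  y <- c(1, 2, 3)
  expect_equal(evaluate_predictions(y, y, "prediction")$R2, 1)
  expect_equal(evaluate_predictions(y, y, "prediction")$RMSE, 0)
  ev0 <- evaluate_predictions(y, rep(mean(y), 3), "calibration")
  expect_equal(ev0$R2, 0)
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 4), "prediction")
  expect_equal(ev$RMSE, sqrt(1 / 3))
  # R2/RMSE consistency: RMSE^2 = (1 - R2) * mean squared deviation
  set.seed(17)
  yt <- rnorm(50)
  yh <- yt + rnorm(50, 0, 0.3)
  e <- evaluate_predictions(yt, yh, "validation")
  expect_equal(e$RMSE^2, (1 - e$R2) * mean((yt - mean(yt))^2),
               tolerance = 1e-12)
  expect_warning(evaluate_predictions(c(1, 1), c(1, 2)), "undefined")
})
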