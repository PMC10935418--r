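#' Partial least-squares regression (single response)
#'
#' Mean-centered NIPALS decomposition for a single response: factors are
#' extracted one at a time, each maximizing covariance between the X
#' scores and the response, with X deflated after every factor (the
#' standard single-y shortcut; with one response the inner iteration
#' converges in a single step, so no iteration loop is needed).  The
#' factorization is `X = T P' + E`, `y = T q + f`, and the model also
#' carries the collapsed regression coefficients in original band space
#' for every factor count `1..F`, so predictions at any factor count cost
#' one matrix product.
#'
#' Factor extraction halts early when the residual covariance or score
#' variance falls below `tol` times its initial scale; the achieved
#' factor count is stored in `n_factors`.
#'
#' @param X numeric matrix (samples x bands) or a [spectra_table()].
#' @param y response vector (ignored when `X` is a `spectra_table`).
#' @param n_factors number of latent variables requested; capped at
#'   `min(n - 1, n_bands, 20)`.
#' @param tol relative tolerance for early stopping (default `1e-12`).
#' @return An object of class `pls_model` with elements `n_factors`
#'   (achieved), `x_mean`, `y_mean`, `weights` (W), `x_loadings` (P),
#'   `y_loadings` (q), `x_scores` (T), `y_scores` (U), `inner_coef` (B),
#'   `coefficients` (bands x factors, cumulative), `intercepts`,
#'   `residual_x_fro`, `residual_y_ss`.
#' @examples
#' m <- pls_fit(matrix(1:3), c(2, 4, 6), 1)
#' predict(m, matrix(1:3))  # 2 4 6
#' @export
pls_fit <- function(X, y = NULL, n_factors = 10, tol = 1e-12) {
  if (inherits(X, "spectra_table")) {
    y <- X$ssc
    X <- X$X
  }
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, n >= 2, p >= 1, n_factors >= 1)
  if (stats::var(y) == 0) {
    stop("response has zero variance")
  }
  n_factors <- min(n_factors, n - 1L, p, 20L)

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean

  W <- P <- matrix(0, p, n_factors)
  Tm <- U <- matrix(0, n, n_factors)
  q <- numeric(n_factors)
  s0 <- sqrt(sum(crossprod(Xc, yc)^2))
  a <- 0L
  Xr <- Xc
  yr <- yc
  while (a < n_factors) {
    s <- crossprod(Xr, yr)
    sn <- sqrt(sum(s^2))
    if (sn <= tol * max(s0, 1)) break
    w <- s / sn
    t <- Xr %*% w
    tt <- sum(t^2)
    if (tt <= tol) break
    a <- a + 1L
    p_a <- crossprod(Xr, t) / tt
    q_a <- sum(yr * t) / tt
    W[, a] <- w
    P[, a] <- p_a
    q[a] <- q_a
    Tm[, a] <- t
    U[, a] <- yr # response scores before deflation (single-y convention)
    Xr <- Xr - tcrossprod(t, p_a)
    yr <- yr - q_a * t
  }
  if (a == 0L) {
    stop("no PLS factor could be extracted (X uncorrelated with y?)")
  }
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  U <- U[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]

  # collapsed coefficients for every factor count via R = W (P'W)^-1
  R <- matrix(0, p, a)
  B <- matrix(0, p, a)
  for (j in seq_len(a)) {
    r <- W[, j]
    if (j > 1) {
      r <- r - R[, seq_len(j - 1), drop = FALSE] %*%
        crossprod(P[, seq_len(j - 1), drop = FALSE], W[, j])
    }
    R[, j] <- r
    B[, j] <- (if (j > 1) B[, j - 1] else 0) + r * q[j]
  }
  intercepts <- y_mean - drop(crossprod(x_mean, B))

  structure(
    list(
      n_factors = a, requested_factors = n_factors,
      x_mean = x_mean, y_mean = y_mean,
      weights = W, x_loadings = P, y_loadings = q,
      x_scores = Tm, y_scores = U, inner_coef = q,
      coefficients = B, intercepts = intercepts,
      residual_x_fro = sqrt(sum(Xr^2)), residual_y_ss = sum(yr^2)
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf(
    "<pls_model> %d factors, %d bands\n", x$n_factors, nrow(x$coefficients)
  ))
  invisible(x)
}

#' Predict from a PLS model
#'
#' `y_hat = X_new %*% coefficients + intercept` at the chosen factor
#' count.  `n_factors = 0` gives the null model (constant training mean).
#'
#' @param object a [pls_fit()] model.
#' @param newdata numeric matrix (samples x bands) or [spectra_table()].
#' @param n_factors factor count to use (default: the model's).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_factors = NULL, ...) {
  if (inherits(newdata, "spectra_table")) newdata <- newdata$X
  newdata <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  f <- if (is.null(n_factors)) object$n_factors else n_factors
  if (f > object$n_factors || f < 0) {
    stop(sprintf("model holds %d factors; %d requested", object$n_factors, f))
  }
  if (ncol(newdata) != nrow(object$coefficients)) {
    stop(sprintf(
      "newdata has %d bands but the model expects %d",
      ncol(newdata), nrow(object$coefficients)
    ))
  }
  if (f == 0) {
    return(rep(object$y_mean, nrow(newdata)))
  }
  drop(newdata %*% object$coefficients[, f] + object$intercepts[f])
}

# Kernel PLS1 on centered cross-products (Dayal-MacGregor, X'y deflation
# only).  Returns the (p x F) cumulative coefficient matrix; columns past
# the achieved rank repeat the last extracted column.  Equivalent to
# NIPALS on the centered data; O(p^2) per factor, so cross-validation
# folds can reuse downdated cross-products instead of refitting from X.
.pls_coef_kernel <- function(Cxx, Cxy, max_f, tol = 1e-12) {
  p <- length(Cxy)
  max_f <- min(max_f, p)
  R <- P <- matrix(0, p, max_f)
  B <- matrix(0, p, max_f)
  s <- Cxy
  s0 <- sqrt(sum(Cxy^2))
  a <- 0L
  while (a < max_f) {
    sn <- sqrt(sum(s^2))
    if (sn <= tol * max(s0, 1)) break
    w <- s / sn
    r <- w
    if (a > 0) {
      r <- w - R[, seq_len(a), drop = FALSE] %*%
        crossprod(P[, seq_len(a), drop = FALSE], w)
    }
    Ar <- Cxx %*% r
    tt <- drop(crossprod(r, Ar))
    if (tt <= tol * max(sum(diag(Cxx)), 1)) break
    a <- a + 1L
    P[, a] <- Ar / tt
    q_a <- drop(crossprod(r, s)) / tt
    R[, a] <- r
    B[, a] <- (if (a > 1) B[, a - 1] else 0) + r * q_a
    s <- s - P[, a] * (tt * q_a)
  }
  if (a == 0L) {
    return(B) # all-zero: null model
  }
  if (a < max_f) {
    B[, seq(a + 1L, max_f)] <- B[, a]
  }
  B
}

#' Cross-validated factor selection
#'
#' Computes the cross-validated RMSE (RMSECV) for every factor count
#' `1..max_factors` under leave-one-out or seeded k-fold splitting, and
#' selects the factor count minimizing RMSECV (ties broken toward fewer
#' factors).  Held-out fits reuse downdated cross-product matrices, so a
#' full leave-one-out sweep costs `n` kernel fits of `O(bands^2)` per
#' factor rather than `n` NIPALS passes over the data.
#'
#' @param X numeric matrix (samples x bands) or a [spectra_table()].
#' @param y response vector (ignored for a `spectra_table`).
#' @param max_factors largest factor count examined; capped at
#'   `min(n - 2, n_bands, 20)`.
#' @param scheme `"loo"` (default) or `"kfold"`.
#' @param k number of folds for `scheme = "kfold"` (default 5).
#' @param seed optional seed for the k-fold shuffle; `NULL` uses the
#'   current RNG stream.
#' @param folds optional list of held-out index vectors, overriding
#'   `scheme`; lets a caller reuse one fold assignment across many calls
#'   so RMSECV values are paired.
#' @return List with `rmsecv` (vector over factor counts),
#'   `optimal_factors`, `press`, `cv_predictions` (n x max_factors
#'   matrix of held-out predictions) and `scheme`.
#' @export
pls_cv <- function(X, y = NULL, max_factors = 20,
                   scheme = c("loo", "kfold"), k = 5, seed = NULL,
                   folds = NULL) {
  if (inherits(X, "spectra_table")) {
    y <- X$ssc
    X <- X$X
  }
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n)
  if (scheme == "loo" && n < 3) {
    stop("leave-one-out cross-validation needs at least 3 samples")
  }
  max_factors <- min(max_factors, n - 2L, p, 20L)
  if (max_factors < 1) stop("too few samples/bands for cross-validation")

  if (is.null(folds)) {
    folds <- if (scheme == "loo") {
      as.list(seq_len(n))
    } else {
      if (!is.null(seed)) set.seed(seed)
      split(sample(n), rep_len(seq_len(k), n))
    }
  }

  Sxx <- crossprod(X)
  Sxy <- drop(crossprod(X, y))
  Sx <- colSums(X)
  Sy <- sum(y)

  cv_pred <- matrix(NA_real_, n, max_factors)
  for (fold in folds) {
    Xh <- X[fold, , drop = FALSE]
    yh <- y[fold]
    ntr <- n - length(fold)
    mx <- (Sx - colSums(Xh)) / ntr
    my <- (Sy - sum(yh)) / ntr
    Cxx <- Sxx - crossprod(Xh) - ntr * tcrossprod(mx)
    Cxy <- Sxy - drop(crossprod(Xh, yh)) - ntr * mx * my
    B <- .pls_coef_kernel(Cxx, Cxy, max_factors)
    cv_pred[fold, ] <- sweep(Xh, 2, mx) %*% B + my
  }
  press <- colSums((cv_pred - y)^2)
  rmsecv <- sqrt(press / n)
  list(
    rmsecv = rmsecv,
    # ties (to rounding, relative or absolute on the response scale)
    # broken toward fewer factors
    optimal_factors = which(
      rmsecv <= min(rmsecv) + max(1e-8 * min(rmsecv),
                                  1e-10 * stats::sd(y))
    )[1],
    press = press,
    cv_predictions = cv_pred,
    scheme = scheme
  )
}

#' Random calibration/prediction split
#'
#' Uniform seed-reproducible partition.  The calibration size is
#' `round(fraction * n)` with halves rounded away from zero, so 648
#' samples at 0.7 split 454/194 and 631 split 442/189.  With
#' `group_by_fruit = TRUE` whole fruits (both orientations) are assigned
#' to the same side, avoiding replicate leakage, at the cost of the split
#' sizes being approximate.
#'
#' @param table a [spectra_table()].
#' @param fraction calibration fraction in (0, 1); default 0.7.
#' @param seed optional RNG seed.
#' @param group_by_fruit keep orientation replicates of a fruit together.
#' @return List with `calibration` and `prediction` tables plus the index
#'   vectors `calibration_idx` and `prediction_idx`.
#' @export
split_dataset <- function(table, fraction = 0.7, seed = NULL,
                          group_by_fruit = FALSE) {
  stopifnot(inherits(table, "spectra_table"), fraction > 0, fraction < 1)
  n <- nrow(table$X)
  if (n < 2) stop("need at least 2 samples to split")
  n_cal <- floor(fraction * n + 0.5) # round half away from zero
  if (n_cal < 1 || n_cal >= n) {
    stop(sprintf("fraction %.3f gives an empty partition for n = %d",
                 fraction, n))
  }
  if (!is.null(seed)) set.seed(seed)
  if (group_by_fruit) {
    fruits <- sample(unique(table$fruit_id))
    counts <- table(table$fruit_id)[as.character(fruits)]
    n_fruit_cal <- which(cumsum(counts) >= n_cal)[1]
    cal_idx <- which(table$fruit_id %in% fruits[seq_len(n_fruit_cal)])
  } else {
    cal_idx <- sort(sample(n, n_cal))
  }
  pred_idx <- setdiff(seq_len(n), cal_idx)
  list(
    calibration = table[cal_idx, ], prediction = table[pred_idx, ],
    calibration_idx = cal_idx, prediction_idx = pred_idx
  )
}

#' R-squared and RMSE of a prediction set
#'
#' `RMSE = sqrt(mean((y - y_hat)^2))`; `R2 = 1 - SSres / SStot` with the
#' total sum of squares taken about the mean of `y_true` itself (not the
#' squared correlation), so a constant prediction at the mean scores 0.
#'
#' @param y_true reference values (length >= 2).
#' @param y_hat predictions, same length.
#' @param label one of `"calibration"`, `"validation"`, `"prediction"`.
#' @return List with `label`, `n`, `R2`, `RMSE`.
#' @export
evaluate_predictions <- function(y_true, y_hat,
                                 label = c("calibration", "validation",
                                           "prediction")) {
  label <- match.arg(label)
  stopifnot(length(y_true) == length(y_hat), length(y_true) >= 2)
  ss_res <- sum((y_true - y_hat)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in y_true: R2 undefined")
    NA_real_
  } else {
    1 - ss_res / ss_tot
  }
  list(label = label, n = length(y_true), R2 = r2,
       RMSE = sqrt(ss_res / length(y_true)))
}
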