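#' Spectral preprocessing
#'
#' The preprocessing transforms routinely compared in diffuse-reflectance
#' chemometrics, applied row-wise to a spectra matrix: moving-average
#' smoothing, Savitzky-Golay first derivative, maximum / mean / range
#' normalization, the standard normal variate (SNV) and multiplicative
#' scatter correction (MSC).  All transforms preserve spectrum length and
#' band order.  Every transform except MSC is purely per-row; MSC fits a
#' reference spectrum (the column-wise mean of the data it is fitted on)
#' which must be learned on calibration spectra only and frozen for later
#' prediction rows -- hence the fit/apply split of [fit_preprocessor()]
#' and [apply_preprocessor()].
#'
#' The smoothing/derivative window is given as a gap size in nm and
#' interpreted, by default, as a half-width: at 2 nm resolution a 6 nm
#' gap gives a 7-point window (center plus/minus 3 bands).  Set
#' `gap_mode = "total_width"` for the narrower reading (6 nm total span,
#' 3 points).
#'
#' @param method one of `"none"`, `"moving_average"`,
#'   `"sg_first_derivative"`, `"norm_max"`, `"norm_mean"`, `"norm_range"`,
#'   `"snv"`, `"msc"`.
#' @param window_nm gap size (nm) for smoothing/derivative methods
#'   (default 6); must be a positive multiple of the grid step.
#' @param poly_order Savitzky-Golay polynomial order (default 2).
#' @param gap_mode `"half_width"` (default) or `"total_width"`.
#' @return `preprocessor()` returns an object of class `preprocessor`;
#'   it must be passed through [fit_preprocessor()] before use.
#' @examples
#' pp <- preprocessor("snv")
#' @export
preprocessor <- function(method = c("none", "moving_average",
                                    "sg_first_derivative", "norm_max",
                                    "norm_mean", "norm_range", "snv", "msc"),
                         window_nm = 6, poly_order = 2,
                         gap_mode = c("half_width", "total_width")) {
  method <- match.arg(method)
  gap_mode <- match.arg(gap_mode)
  stopifnot(window_nm > 0, poly_order >= 1)
  structure(
    list(method = method, window_nm = window_nm, poly_order = poly_order,
         gap_mode = gap_mode, msc_reference = NULL, fitted = FALSE),
    class = "preprocessor"
  )
}

# odd window length in points for a gap given in nm
.window_points <- function(window_nm, step_nm, gap_mode) {
  k <- window_nm / step_nm
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf(
      "window of %g nm is not a multiple of the %g nm grid step",
      window_nm, step_nm
    ))
  }
  k <- as.integer(round(k))
  # half_width: gap on each side of the center; total_width: full span
  pts <- if (gap_mode == "half_width") 2L * k + 1L else k + (k %% 2L == 0L)
  max(pts, 3L)
}

#' Moving-average smoothing of one spectrum
#'
#' Centered running mean with an odd window; near the ends the window
#' shrinks symmetrically so the output keeps full length.
#'
#' @param x numeric spectrum.
#' @param window_nm window gap (nm); see [preprocessor()].
#' @param step_nm grid step (nm).
#' @param gap_mode see [preprocessor()].
#' @return Smoothed spectrum, same length.
#' @export
moving_average <- function(x, window_nm = 6, step_nm = 2,
                           gap_mode = "half_width") {
  pts <- .window_points(window_nm, step_nm, gap_mode)
  n <- length(x)
  if (pts > n) {
    stop(sprintf("window of %d points wider than spectrum (%d)", pts, n))
  }
  half <- (pts - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  # windows shrink at the ends: mean over the in-range part of the window
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Savitzky-Golay first derivative of one spectrum
#'
#' Local polynomial least-squares first derivative in reflectance units
#' per nm, so output is resolution-independent.  End points use the
#' polynomial fits of the edge windows, making the filter exact on
#' polynomials up to `poly_order` over the whole spectrum.
#'
#' @inheritParams moving_average
#' @param poly_order polynomial order (default 2); the window must hold
#'   at least `poly_order + 2` points.
#' @return Derivative spectrum (per nm), same length.
#' @export
sg_first_derivative <- function(x, window_nm = 6, step_nm = 2,
                                poly_order = 2, gap_mode = "half_width") {
  pts <- .window_points(window_nm, step_nm, gap_mode)
  if (pts < poly_order + 2) {
    pts <- poly_order + 2L + ((poly_order + 2L) %% 2L == 0L)
  }
  if (pts > length(x)) {
    stop(sprintf("spectrum too short (%d points) for a %d-point window",
                 length(x), pts))
  }
  signal::sgolayfilt(x, p = poly_order, n = pts, m = 1, ts = step_nm)
}

#' Per-spectrum normalizations
#'
#' `max`: divide by the spectrum maximum; `mean`: divide by the mean;
#' `range`: rescale to `[0, 1]` via `(x - min) / (max - min)`.
#'
#' @param x numeric spectrum.
#' @param mode `"max"`, `"mean"` or `"range"`.
#' @return Normalized spectrum, same length.
#' @export
normalize_spectrum <- function(x, mode = c("max", "mean", "range")) {
  mode <- match.arg(mode)
  switch(mode,
    max = {
      if (max(x) == 0) stop("maximum normalization: spectrum maximum is zero")
      x / max(x)
    },
    mean = {
      if (mean(x) == 0) stop("mean normalization: spectrum mean is zero")
      x / mean(x)
    },
    range = {
      if (max(x) <= min(x)) stop("range normalization: spectrum has no spread")
      (x - min(x)) / (max(x) - min(x))
    }
  )
}

#' Standard normal variate
#'
#' Centers each spectrum and scales it to unit sample standard deviation
#' (n - 1 denominator, the chemometrics convention), removing per-sample
#' multiplicative gain and additive offset.
#'
#' @param x numeric spectrum of length >= 2.
#' @return SNV-transformed spectrum (mean 0, sd 1).
#' @export
snv <- function(x) {
  if (length(x) < 2) stop("SNV needs at least 2 points")
  s <- stats::sd(x)
  if (s == 0) stop("SNV: constant spectrum has no spread")
  (x - mean(x)) / s
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed on a reference spectrum by ordinary least
#' squares, `x ~ a + b * reference`, and corrected to `(x - a) / b`,
#' removing per-sample scatter gain and offset.  The reference defaults
#' to the column-wise mean of `X` and is returned so prediction spectra
#' can be corrected against the calibration reference.
#'
#' @param X numeric matrix (samples x bands).
#' @param reference optional reference spectrum; if `NULL`, the column
#'   mean of `X` is used (requires >= 2 rows).
#' @return List with `X` (corrected matrix) and `reference`.
#' @export
msc <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (is.null(reference)) {
    if (nrow(X) < 2) stop("MSC needs >= 2 spectra to build a reference")
    reference <- colMeans(X)
  }
  stopifnot(length(reference) == ncol(X))
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) stop("MSC reference spectrum is constant")
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    b <- sum((x - mean(x)) * rc) / denom
    if (abs(b) < 1e-12) {
      stop(sprintf("MSC: spectrum %d has no component along the reference", i))
    }
    a <- mean(x) - b * mean(reference)
    out[i, ] <- (x - a) / b
  }
  list(X = out, reference = reference)
}

#' Fit a preprocessor on calibration spectra
#'
#' For MSC this learns the reference spectrum from the calibration rows;
#' all other methods have nothing to learn and are marked fitted as-is.
#'
#' @param pp a [preprocessor()].
#' @param X calibration spectra matrix (samples x bands).
#' @return The fitted `preprocessor`.
#' @export
fit_preprocessor <- function(pp, X) {
  stopifnot(inherits(pp, "preprocessor"))
  if (pp$method == "msc") {
    pp$msc_reference <- colMeans(as.matrix(X))
  }
  pp$fitted <- TRUE
  pp
}

#' Apply a fitted preprocessor to spectra
#'
#' @param pp a fitted [preprocessor()].
#' @param X spectra matrix (samples x bands) or a single spectrum.
#' @param step_nm grid step (nm), needed by the windowed methods.
#' @return Transformed matrix with the same shape.
#' @export
apply_preprocessor <- function(pp, X, step_nm = 2) {
  stopifnot(inherits(pp, "preprocessor"))
  if (!pp$fitted) stop("preprocessor must be fitted first (fit_preprocessor)")
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  out <- switch(pp$method,
    none = X,
    moving_average = t(apply(X, 1, moving_average, window_nm = pp$window_nm,
                             step_nm = step_nm, gap_mode = pp$gap_mode)),
    sg_first_derivative = t(apply(X, 1, sg_first_derivative,
                                  window_nm = pp$window_nm, step_nm = step_nm,
                                  poly_order = pp$poly_order,
                                  gap_mode = pp$gap_mode)),
    norm_max = t(apply(X, 1, normalize_spectrum, mode = "max")),
    norm_mean = t(apply(X, 1, normalize_spectrum, mode = "mean")),
    norm_range = t(apply(X, 1, normalize_spectrum, mode = "range")),
    snv = t(apply(X, 1, snv)),
    msc = msc(X, reference = pp$msc_reference)$X
  )
  dimnames(out) <- dimnames(X)
  out
}

#' Preprocess a spectra table
#'
#' Convenience wrapper: fits `pp` on `fit_table` (default: the table
#' itself) and applies it to `table`, keeping identifiers and references.
#'
#' @param table a [spectra_table()].
#' @param pp a [preprocessor()] (fitted or not).
#' @param fit_table table whose rows define any fitted quantities
#'   (MSC reference); defaults to `table`.
#' @return List with the transformed `table` and the fitted `pp`.
#' @export
preprocess_table <- function(table, pp, fit_table = table) {
  stopifnot(inherits(table, "spectra_table"))
  step <- if (length(table$wavelengths) > 1) diff(table$wavelengths[1:2]) else 2
  if (!pp$fitted) pp <- fit_preprocessor(pp, fit_table$X)
  Xt <- apply_preprocessor(pp, table$X, step_nm = step)
  out <- spectra_table(Xt, table$ssc, table$wavelengths,
                       fruit_id = table$fruit_id,
                       orientation = table$orientation)
  for (a in c("ssc_noise_floor", "template", "noise_sd")) {
    if (!is.null(attr(table, a))) attr(out, a) <- attr(table, a)
  }
  list(table = out, pp = pp)
}
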