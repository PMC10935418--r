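#' Exponentially decreasing retention schedule
#'
#' The enforced-selection schedule of CARS: at sampling run `i` of `N`
#' the fraction of the `p` original bands allowed to survive is
#' `r_i = a * exp(-k * i)` with `a = (p/2)^(1/(N-1))` and
#' `k = log(p/2)/(N-1)`, chosen so that `r_1 = 1` (all bands) and
#' `r_N = 2/p` (two bands): selection starts gentle and ends brutal.
#'
#' @param i sampling run index, `1 <= i <= N`.
#' @param n_mc total number of Monte Carlo sampling runs `N` (>= 2).
#' @param n_bands original band count `p` (>= 3).
#' @return Retention ratio in `(0, 1]`; vectorized over `i`.
#' @examples
#' edf_ratio(1, 100, 300)               # 1
#' round(edf_ratio(100, 100, 300) * 300) # 2
#' @export
edf_ratio <- function(i, n_mc, n_bands) {
  stopifnot(all(i >= 1), all(i <= n_mc), n_mc >= 2)
  if (n_bands < 3) {
    stop("the retention schedule is degenerate for fewer than 3 bands")
  }
  a <- (n_bands / 2)^(1 / (n_mc - 1))
  k <- log(n_bands / 2) / (n_mc - 1)
  a * exp(-k * i)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Effective-wavelength selection for PLS calibration.  Each of `n_mc`
#' Monte Carlo sampling runs: (1) fits a PLS model on a random
#' `mc_fraction` subset of the calibration samples restricted to the
#' currently retained bands, with the factor count picked by k-fold
#' cross-validation on that subset (capped at
#' `min(max_factors, bands - 1)`); (2) enforced selection: only the
#' `round(r_i * p)` bands with the largest absolute collapsed regression
#' coefficients survive, with `r_i` from [edf_ratio()]; (3) adaptive
#' reweighted sampling: `round(r_i * p)` weighted draws with replacement,
#' weights proportional to the absolute coefficients, deduplicated -- so
#' the realized subset is at most the enforced size and competitive among
#' the strong bands; (4) the RMSECV of a PLS model on the full
#' calibration set restricted to the surviving bands is recorded.  The
#' subset with the lowest RMSECV across all runs is selected (ties broken
#' toward the earliest, i.e. largest, subset).
#'
#' If the retained set collapses below 2 bands before run `n_mc`, the
#' iteration sequence is truncated and recorded in the result.  Runs
#' where all coefficients are zero fall back to uniform weights with a
#' warning.
#'
#' @param calibration a [spectra_table()] of calibration samples
#'   (>= 10 rows, >= 3 bands), already preprocessed the same way as the
#'   downstream model.
#' @param n_mc number of Monte Carlo sampling runs (default 100).
#' @param mc_fraction fraction of calibration samples drawn per run
#'   (default 0.8).
#' @param cv_folds folds of the internal cross-validation (default 5).
#' @param max_factors internal PLS factor cap (default 10).
#' @param seed RNG seed; fixed seed gives an identical selection.
#' @return An object of class `cars_result`: `selected_bands` (indices
#'   into the input bands), `selected_nm`, `rmsecv_curve`, `ratio_curve`,
#'   `retained_sets`, `n_iterations`, `best_iteration`, `seed`,
#'   `truncated`.
#' @export
cars_select <- function(calibration, n_mc = 100, mc_fraction = 0.8,
                        cv_folds = 5, max_factors = 10, seed = NULL) {
  stopifnot(inherits(calibration, "spectra_table"))
  X <- calibration$X
  y <- calibration$ssc
  n <- nrow(X)
  p <- ncol(X)
  if (n < 10) stop("CARS needs at least 10 calibration samples")
  if (p < 3) stop("CARS needs at least 3 bands")
  if (!is.null(seed)) set.seed(seed)

  n_sub <- max(2L, round(mc_fraction * n))
  # one fold assignment reused for every run's full-set RMSECV, so the
  # trajectory is a paired comparison rather than fold-reshuffle noise
  full_folds <- split(sample(n), rep_len(seq_len(cv_folds), n))
  retained <- seq_len(p)
  retained_sets <- vector("list", n_mc)
  rmsecv_curve <- rep(NA_real_, n_mc)
  ratio_curve <- edf_ratio(seq_len(n_mc), n_mc, p)
  truncated <- FALSE
  n_done <- 0L

  for (i in seq_len(n_mc)) {
    target <- max(2L, round(ratio_curve[i] * p))
    rows <- sample(n, n_sub)
    Xs <- X[rows, retained, drop = FALSE]
    ys <- y[rows]
    fmax <- min(max_factors, length(retained) - 1L, n_sub - 2L)
    cv_sub <- pls_cv(Xs, ys, max_factors = max(fmax, 1), scheme = "kfold",
                     k = cv_folds)
    fit <- pls_fit(Xs, ys, n_factors = cv_sub$optimal_factors)
    b <- abs(fit$coefficients[, fit$n_factors])

    # enforced selection: largest |coefficient| survive
    keep_n <- min(target, length(retained))
    ord <- order(b, decreasing = TRUE)[seq_len(keep_n)]
    cand <- retained[ord]
    wts <- b[ord]
    if (sum(wts) == 0) {
      warning(sprintf("run %d: all-zero coefficients, uniform weights", i))
      wts <- rep(1, length(cand))
    }
    # adaptive reweighted sampling with replacement, then deduplication
    drawn <- sample(cand, size = target, replace = TRUE, prob = wts / sum(wts))
    retained <- sort(unique(drawn))
    if (length(retained) < 2) {
      truncated <- TRUE
      break
    }
    fmax_full <- min(max_factors, length(retained) - 1L, n - 2L)
    cv_full <- pls_cv(X[, retained, drop = FALSE], y,
                      max_factors = max(fmax_full, 1), scheme = "kfold",
                      k = cv_folds, folds = full_folds)
    retained_sets[[i]] <- retained
    rmsecv_curve[i] <- min(cv_full$rmsecv)
    n_done <- i
  }
  if (n_done == 0L) stop("CARS produced no valid subset")

  best <- which.min(rmsecv_curve[seq_len(n_done)]) # first = earliest run
  selected <- retained_sets[[best]]
  structure(
    list(
      selected_bands = selected,
      selected_nm = calibration$wavelengths[selected],
      rmsecv_curve = rmsecv_curve[seq_len(n_done)],
      ratio_curve = ratio_curve[seq_len(n_done)],
      retained_sets = retained_sets[seq_len(n_done)],
      n_iterations = n_done,
      best_iteration = best,
      seed = seed,
      truncated = truncated
    ),
    class = "cars_result"
  )
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf(
    "<cars_result> %d of %d runs, %d bands selected (run %d, RMSECV %.4g)\n",
    x$n_iterations, length(x$ratio_curve), length(x$selected_bands),
    x$best_iteration, x$rmsecv_curve[x$best_iteration]
  ))
  invisible(x)
}
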