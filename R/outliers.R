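#' Monte Carlo prediction-error outlier detection
#'
#' Screens a spectra table for anomalous samples before calibration.
#' The data are split many times at random into training and test
#' portions; each split fits a PLS model with a fixed factor count on the
#' training rows and records the absolute prediction error of every test
#' row.  A sample that is merely noisy accumulates errors with an
#' ordinary mean and spread; an outlier (bad reference value, corrupted
#' spectrum) shows a high mean error, a high error spread, or both.
#' Samples whose mean error or error standard deviation exceeds the
#' population mean plus `k_sigma` standard deviations of the respective
#' statistic are flagged.
#'
#' The factor count is fixed once, before the runs, by a single
#' leave-one-out cross-validation on the full table (cap 20) unless
#' supplied -- re-selecting factors inside each run would confound the
#' error distributions.  If any sample lands in the test portion fewer
#' than `min_test_appearances` times, additional runs are appended until
#' every sample is covered.
#'
#' @param table a [spectra_table()] with at least 20 rows.
#' @param n_runs number of random splits (default 500).
#' @param train_fraction training share per split, in `[0.5, 1)`
#'   (default 0.75).
#' @param k_sigma flagging threshold in population standard deviations
#'   (default 2.5).
#' @param factor_count PLS factor count used in every run; `NULL`
#'   (default) selects it by one LOOCV on the full table.
#' @param min_test_appearances minimum times each sample must be tested
#'   (default 20).
#' @param seed RNG seed; fixed seed gives a bit-identical report.
#' @return An object of class `outlier_report`: a per-sample data frame
#'   `samples` (`mean_error`, `sd_error`, `times_in_test`, `flag`),
#'   `mean_cutoff`, `sd_cutoff`, `flagged` (indices), plus the run
#'   parameters.
#' @export
mc_outlier_detect <- function(table, n_runs = 500, train_fraction = 0.75,
                              k_sigma = 2.5, factor_count = NULL,
                              min_test_appearances = 20, seed = NULL) {
  stopifnot(inherits(table, "spectra_table"))
  X <- table$X
  y <- table$ssc
  n <- nrow(X)
  if (n < 20) stop("Monte Carlo outlier detection needs at least 20 samples")
  if (train_fraction < 0.5 || train_fraction >= 1) {
    stop("train_fraction must lie in [0.5, 1)")
  }
  if (stats::var(y) == 0) stop("response has zero variance")

  if (is.null(factor_count)) {
    factor_count <- pls_cv(X, y, max_factors = 20)$optimal_factors
  }
  if (!is.null(seed)) set.seed(seed)

  n_train <- max(2L, round(train_fraction * n))
  err_sum <- err_sq <- numeric(n)
  count <- integer(n)
  total_runs <- 0L
  run_batch <- function(runs) {
    for (r in seq_len(runs)) {
      tr <- sample(n, n_train)
      te <- setdiff(seq_len(n), tr)
      fit <- pls_fit(X[tr, , drop = FALSE], y[tr], n_factors = factor_count)
      e <- abs(y[te] - predict(fit, X[te, , drop = FALSE]))
      err_sum[te] <<- err_sum[te] + e
      err_sq[te] <<- err_sq[te] + e^2
      count[te] <<- count[te] + 1L
    }
    total_runs <<- total_runs + runs
  }
  run_batch(n_runs)
  while (any(count < min_test_appearances)) {
    run_batch(max(50L, ceiling(n_runs / 10)))
  }

  mean_error <- err_sum / count
  sd_error <- sqrt(pmax(err_sq - count * mean_error^2, 0) / (count - 1L))
  # degenerate-case floor: exact-fit data leaves only rounding residue,
  # which must not be flagged
  floor_cut <- 1e-8 * stats::sd(y)
  mean_cutoff <- max(mean(mean_error) + k_sigma * stats::sd(mean_error),
                     floor_cut)
  sd_cutoff <- max(mean(sd_error) + k_sigma * stats::sd(sd_error), floor_cut)
  flag <- mean_error > mean_cutoff | sd_error > sd_cutoff

  structure(
    list(
      samples = data.frame(
        sample = seq_len(n), mean_error = mean_error, sd_error = sd_error,
        times_in_test = count, flag = flag
      ),
      mean_cutoff = mean_cutoff, sd_cutoff = sd_cutoff,
      flagged = which(flag),
      n_runs = total_runs, train_fraction = train_fraction,
      k_sigma = k_sigma, factor_count = factor_count, seed = seed
    ),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report> %d of %d samples flagged (%d runs, %d factors, k = %.2g)\n",
    length(x$flagged), nrow(x$samples), x$n_runs, x$factor_count, x$k_sigma
  ))
  invisible(x)
}

#' Drop flagged samples from a table
#'
#' @param table a [spectra_table()].
#' @param report an `outlier_report` computed on the same table.
#' @return The [spectra_table()] without the flagged rows.
#' @export
remove_outliers <- function(table, report) {
  stopifnot(inherits(table, "spectra_table"),
            inherits(report, "outlier_report"),
            nrow(report$samples) == nrow(table$X))
  if (length(report$flagged) == 0) {
    return(table)
  }
  table[-report$flagged, ]
}
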