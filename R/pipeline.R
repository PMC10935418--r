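#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()].  Unknown fields are
#' rejected so typos cannot silently change a run.  The four model
#' variants combine full-spectrum PLSR versus CARS wavelength selection
#' with and without Monte Carlo outlier removal.
#'
#' @param preprocessing character vector of [preprocessor()] methods to
#'   sweep (default `"none"`).
#' @param variants subset of `c("plsr", "cars_plsr", "plsr_outlier",
#'   "cars_plsr_outlier")`; default all four.
#' @param split_fraction calibration share of the 70/30-style split
#'   (default 0.7).
#' @param max_factors factor cap for the final leave-one-out selection
#'   (default 20).
#' @param cars list of [cars_select()] arguments (`n_mc`, `mc_fraction`,
#'   `cv_folds`, `max_factors`).
#' @param outliers list of [mc_outlier_detect()] arguments (`n_runs`,
#'   `train_fraction`, `k_sigma`, `factor_count`).
#' @param window_nm gap size (nm) for windowed preprocessing methods.
#' @param group_by_fruit keep orientation replicates together when
#'   splitting (default FALSE).
#' @param seed base RNG seed for the whole run; stage seeds are derived
#'   from it (default 1).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocessing = "none",
                            variants = c("plsr", "cars_plsr",
                                         "plsr_outlier",
                                         "cars_plsr_outlier"),
                            split_fraction = 0.7,
                            max_factors = 20,
                            cars = list(),
                            outliers = list(),
                            window_nm = 6,
                            group_by_fruit = FALSE,
                            seed = 1) {
  all_variants <- c("plsr", "cars_plsr", "plsr_outlier", "cars_plsr_outlier")
  variants <- match.arg(variants, all_variants, several.ok = TRUE)
  known_cars <- c("n_mc", "mc_fraction", "cv_folds", "max_factors")
  known_out <- c("n_runs", "train_fraction", "k_sigma", "factor_count")
  if (length(bad <- setdiff(names(cars), known_cars))) {
    stop(sprintf("unknown CARS option(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(bad <- setdiff(names(outliers), known_out))) {
    stop(sprintf("unknown outlier option(s): %s", paste(bad, collapse = ", ")))
  }
  stopifnot(split_fraction > 0, split_fraction < 1, max_factors >= 1)
  structure(
    list(preprocessing = preprocessing, variants = variants,
         split_fraction = split_fraction, max_factors = max_factors,
         cars = cars, outliers = outliers, window_nm = window_nm,
         group_by_fruit = group_by_fruit, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# stage seeds derived from the base seed; kept well below 2^31
.stage_seed <- function(seed, stage) {
  (seed * 7L + switch(stage, outliers = 101L, split = 202L,
                      cars = 303L)) %% 2000000000L
}

#' Run the SSC model-comparison pipeline
#'
#' Executes, for every preprocessing method and model variant in the
#' config, the full calibration workflow:
#' \enumerate{
#'   \item optional Monte Carlo outlier removal on the full table
#'     (screening uses spectra preprocessed on the full table; removal
#'     precedes the split so both model variants see the same cleaned
#'     data);
#'   \item random calibration/prediction split (shared across variants
#'     of the same preprocessing, so comparisons are paired);
#'   \item preprocessing refitted on the calibration rows only and
#'     applied frozen to the prediction rows (only MSC learns anything,
#'     but the rule is uniform), so nothing about the prediction set
#'     leaks into the model;
#'   \item optional CARS effective-wavelength selection on the
#'     calibration set;
#'   \item leave-one-out factor selection (RMSECV minimum, cap
#'     `max_factors`), final PLS fit, and evaluation on the calibration
#'     set (R2_c, RMSEC), the cross-validation (R2_v, RMSEV) and the
#'     prediction set (R2_p, RMSEP).
#' }
#'
#' @param table a [spectra_table()], or the path of a spectra CSV in the
#'   [write_spectra_csv()] layout.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the report CSV and
#'   per-run JSON artifacts (model, CARS, outliers, coefficients,
#'   true-versus-predicted scatter) are written there.
#' @return An object of class `pipeline_result`: `report` (one row per
#'   variant x preprocessing), `details` (per-run models and stage
#'   outputs) and the `config`.
#' @export
run_pipeline <- function(table, config = pipeline_config(), out_dir = NULL) {
  if (is.character(table)) table <- read_spectra_csv(table)
  stopifnot(inherits(table, "spectra_table"),
            inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  rows <- list()
  details <- list()
  for (pp_method in config$preprocessing) {
    # outlier screening once per preprocessing method, shared by the
    # two outlier-removing variants
    od <- NULL
    cleaned <- NULL
    if (any(grepl("outlier", config$variants))) {
      pp_full <- preprocess_table(
        table, preprocessor(pp_method, window_nm = config$window_nm)
      )$table
      od <- do.call(mc_outlier_detect, c(
        list(table = pp_full, seed = .stage_seed(config$seed, "outliers")),
        config$outliers
      ))
      keep <- setdiff(seq_len(nrow(table$X)), od$flagged)
      cleaned <- table[keep, ]
    }
    for (variant in config$variants) {
      with_od <- grepl("outlier", variant)
      with_cars <- grepl("cars", variant)
      dat <- if (with_od) cleaned else table
      res <- .run_single(dat, pp_method, with_cars, config)
      run <- c(res, list(outliers = if (with_od) od))
      run_id <- paste(variant, pp_method, sep = ".")
      details[[run_id]] <- run
      rows[[run_id]] <- data.frame(
        model = variant, preprocessing = pp_method,
        R2_c = res$eval_c$R2, RMSEC = res$eval_c$RMSE,
        R2_v = res$R2_v, RMSEV = res$RMSEV,
        R2_p = res$eval_p$R2, RMSEP = res$eval_p$RMSE,
        optimal_factors = res$optimal_factors,
        n_bands = length(res$bands),
        n_cal = res$n_cal, n_pred = res$n_pred,
        n_outliers_removed = if (with_od) length(od$flagged) else 0L
      )
    }
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- structure(
    list(report = report, details = details, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) .write_artifacts(out, out_dir)
  out
}

.run_single <- function(table, pp_method, with_cars, config) {
  split <- split_dataset(table, fraction = config$split_fraction,
                         seed = .stage_seed(config$seed, "split"),
                         group_by_fruit = config$group_by_fruit)
  pp <- preprocessor(pp_method, window_nm = config$window_nm)
  fitted <- preprocess_table(split$calibration, pp)
  cal <- fitted$table
  pred <- preprocess_table(split$prediction, fitted$pp)$table

  bands <- seq_len(ncol(cal$X))
  cars_res <- NULL
  if (with_cars) {
    cars_res <- do.call(cars_select, c(
      list(calibration = cal, seed = .stage_seed(config$seed, "cars")),
      config$cars
    ))
    bands <- cars_res$selected_bands
    cal <- cal[, bands]
    pred <- pred[, bands]
  }

  cv <- pls_cv(cal, max_factors = config$max_factors, scheme = "loo")
  f_opt <- cv$optimal_factors
  fit <- pls_fit(cal, n_factors = f_opt)
  yhat_c <- predict(fit, cal)
  yhat_p <- predict(fit, pred)
  eval_c <- evaluate_predictions(cal$ssc, yhat_c, "calibration")
  eval_p <- evaluate_predictions(pred$ssc, yhat_p, "prediction")
  cv_eval <- evaluate_predictions(cal$ssc, cv$cv_predictions[, f_opt],
                                  "validation")
  list(
    model = fit, pp = fitted$pp, cars = cars_res, bands = bands,
    split = list(calibration_idx = split$calibration_idx,
                 prediction_idx = split$prediction_idx),
    optimal_factors = f_opt, rmsecv = cv$rmsecv,
    R2_v = cv_eval$R2, RMSEV = cv_eval$RMSE,
    eval_c = eval_c, eval_p = eval_p,
    n_cal = nrow(cal$X), n_pred = nrow(pred$X),
    scatter = data.frame(ssc_true = pred$ssc, ssc_pred = yhat_p),
    wavelengths = cal$wavelengths
  )
}

.write_artifacts <- function(result, out_dir) {
  utils::write.csv(result$report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  cfg <- result$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (run_id in names(result$details)) {
    run <- result$details[[run_id]]
    m <- run$model
    jsonlite::write_json(
      list(
        n_factors = run$optimal_factors,
        coefficients = as.numeric(m$coefficients[, run$optimal_factors]),
        intercept = m$intercepts[run$optimal_factors],
        x_mean = as.numeric(m$x_mean), y_mean = m$y_mean,
        bands = run$bands, wavelengths = run$wavelengths,
        preprocessing = run$pp$method
      ),
      file.path(out_dir, paste0(run_id, ".model.json")),
      auto_unbox = TRUE, digits = NA
    )
    utils::write.csv(
      data.frame(wavelength_nm = run$wavelengths,
                 coefficient = as.numeric(
                   m$coefficients[, run$optimal_factors]
                 )),
      file.path(out_dir, paste0(run_id, ".coefficients.csv")),
      row.names = FALSE
    )
    utils::write.csv(run$scatter,
                     file.path(out_dir, paste0(run_id, ".scatter.csv")),
                     row.names = FALSE)
    if (!is.null(run$cars)) {
      jsonlite::write_json(
        list(selected_bands = run$cars$selected_bands,
             selected_nm = run$cars$selected_nm,
             rmsecv_curve = run$cars$rmsecv_curve,
             best_iteration = run$cars$best_iteration),
        file.path(out_dir, paste0(run_id, ".cars.json")),
        auto_unbox = TRUE, digits = NA
      )
    }
    if (!is.null(run$outliers)) {
      jsonlite::write_json(
        list(flagged = run$outliers$flagged,
             mean_cutoff = run$outliers$mean_cutoff,
             sd_cutoff = run$outliers$sd_cutoff,
             n_runs = run$outliers$n_runs),
        file.path(out_dir, paste0(run_id, ".outliers.json")),
        auto_unbox = TRUE, digits = NA
      )
    }
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d runs\n", nrow(x$report)))
  print(x$report, digits = 3)
  invisible(x)
}

#' Rank model reports and flag the optimal model
#'
#' Orders pipeline report rows by validation performance -- highest R2_v
#' first, ties broken by lowest RMSEV -- and flags the winner.  Rows
#' with missing R2_v are excluded with a warning.
#'
#' @param report the `report` data frame of a [run_pipeline()] result
#'   (or a `pipeline_result` itself).
#' @return The report sorted, with a logical `optimal` column.
#' @export
compare_models <- function(report) {
  if (inherits(report, "pipeline_result")) report <- report$report
  stopifnot(is.data.frame(report), nrow(report) >= 1,
            all(c("R2_v", "RMSEV") %in% names(report)))
  bad <- is.na(report$R2_v)
  if (any(bad)) {
    warning(sprintf("excluding %d report row(s) with missing R2_v", sum(bad)))
    report <- report[!bad, , drop = FALSE]
  }
  if (nrow(report) == 0) stop("no rows with a valid R2_v")
  report <- report[order(-report$R2_v, report$RMSEV), , drop = FALSE]
  report$optimal <- seq_len(nrow(report)) == 1
  rownames(report) <- NULL
  report
}
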