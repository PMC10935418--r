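#' Table of per-sample mean spectra with SSC references
#'
#' The working container of the chemometric stages: a numeric matrix `X`
#' of per-sample spectra (rows = samples, columns = bands), the reference
#' soluble-solid contents `ssc` (degrees Brix), per-sample fruit
#' identifiers and orientation labels (two scans per fruit: stem and
#' calyx end), and the band-center wavelengths.
#'
#' @param X numeric matrix (samples x bands), finite.
#' @param ssc numeric vector of reference SSC (degrees Brix), one per row.
#' @param wavelengths numeric vector of band centers (nm), one per column.
#' @param fruit_id identifier per row (defaults to row number).
#' @param orientation label per row (default `"a"`).
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(X, ssc, wavelengths,
                          fruit_id = seq_len(nrow(X)),
                          orientation = rep("a", nrow(X))) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), is.numeric(ssc), is.numeric(wavelengths))
  if (nrow(X) != length(ssc)) {
    stop("row count of X must equal length of ssc")
  }
  if (ncol(X) != length(wavelengths)) {
    stop("column count of X must equal length of wavelengths")
  }
  if (any(!is.finite(X)) || any(!is.finite(ssc))) {
    stop("spectra and SSC references must be finite")
  }
  stopifnot(length(fruit_id) == nrow(X), length(orientation) == nrow(X))
  colnames(X) <- paste0("R_", format(wavelengths, trim = TRUE))
  structure(
    list(X = X, ssc = as.numeric(ssc), wavelengths = as.numeric(wavelengths),
         fruit_id = fruit_id, orientation = as.character(orientation)),
    class = "spectra_table"
  )
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf(
    "<spectra_table> %d spectra x %d bands (%g-%g nm), SSC %.2f-%.2f Brix\n",
    nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths),
    min(x$ssc), max(x$ssc)
  ))
  invisible(x)
}

#' @export
dim.spectra_table <- function(x) dim(x$X)

#' Subset a spectra table
#'
#' @param x a [spectra_table()].
#' @param i row (sample) index vector.
#' @param j optional column (band) index vector.
#' @param ... unused.
#' @return The subsetted [spectra_table()]; generator attributes
#'   (`ssc_noise_floor`, `template`) are carried along.
#' @export
`[.spectra_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_len(ncol(x$X))
  out <- spectra_table(
    x$X[i, j, drop = FALSE], x$ssc[i], x$wavelengths[j],
    fruit_id = x$fruit_id[i], orientation = x$orientation[i]
  )
  for (a in c("ssc_noise_floor", "template", "noise_sd")) {
    if (!is.null(attr(x, a))) attr(out, a) <- attr(x, a)
  }
  out
}

#' Read/write spectra tables as CSV
#'
#' The CSV layout has columns `sample_id`, `fruit_id`, `orientation`,
#' `ssc`, then one reflectance column per band named by its center
#' (`R_400`, `R_402`, ...).
#'
#' @param table a [spectra_table()].
#' @param path CSV file path.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` returns a [spectra_table()].
#' @name spectra_csv
NULL

#' @rdname spectra_csv
#' @export
write_spectra_csv <- function(table, path) {
  stopifnot(inherits(table, "spectra_table"))
  df <- data.frame(
    sample_id = seq_len(nrow(table$X)),
    fruit_id = table$fruit_id,
    orientation = table$orientation,
    ssc = table$ssc,
    check.names = FALSE
  )
  df <- cbind(df, as.data.frame(table$X, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  band_cols <- grep("^R_", names(df))
  if (length(band_cols) == 0) {
    stop("no R_<nm> band columns found")
  }
  wl <- as.numeric(sub("^R_", "", names(df)[band_cols]))
  spectra_table(
    as.matrix(df[, band_cols, drop = FALSE]), df$ssc, wl,
    fruit_id = df$fruit_id, orientation = df$orientation
  )
}
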