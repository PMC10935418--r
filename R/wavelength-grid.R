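#' Construct a uniform wavelength grid
#'
#' Band centers of a line-scan VNIR spectrograph are modelled as a uniform
#' grid over a half-open interval `[start_nm, stop_nm)`: centers are
#' `start_nm, start_nm + step_nm, ...`, giving
#' `(stop_nm - start_nm) / step_nm` bands.  The default instrument layout
#' used throughout this package is 400--1000 nm at 2 nm resolution,
#' i.e. 300 bands.
#'
#' @param start_nm first band center (nm).
#' @param stop_nm exclusive upper edge (nm); must exceed `start_nm`.
#' @param step_nm band spacing (nm), positive; `(stop_nm - start_nm)` must
#'   be an integer multiple of `step_nm`.
#'
#' @return An object of class `wavelength_grid`: a list with `start_nm`,
#'   `stop_nm`, `step_nm` and the vector of band `centers`.
#' @examples
#' g <- wavelength_grid(400, 1000, 2)
#' length(g$centers)  # 300
#' @export
wavelength_grid <- function(start_nm = 400, stop_nm = 1000, step_nm = 2) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (stop_nm <= start_nm) {
    stop("`stop_nm` must exceed `start_nm`")
  }
  if (step_nm <= 0) {
    stop("`step_nm` must be positive")
  }
  n <- (stop_nm - start_nm) / step_nm
  if (abs(n - round(n)) > 1e-9) {
    stop(sprintf(
      "wavelength range %g nm is not divisible by step %g nm",
      stop_nm - start_nm, step_nm
    ))
  }
  n <- as.integer(round(n))
  structure(
    list(
      start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
      centers = start_nm + step_nm * (seq_len(n) - 1)
    ),
    class = "wavelength_grid"
  )
}

#' @export
length.wavelength_grid <- function(x) length(x$centers)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %g-%g nm, step %g nm, %d bands\n",
    x$start_nm, x$stop_nm, x$step_nm, length(x$centers)
  ))
  invisible(x)
}

#' Index of the band nearest a target wavelength
#'
#' @param grid a [wavelength_grid()].
#' @param nm target wavelength (nm); must lie within `step_nm` of the grid.
#' @return integer band index.
#' @export
band_index <- function(grid, nm) {
  stopifnot(inherits(grid, "wavelength_grid"), is.numeric(nm), length(nm) == 1)
  i <- which.min(abs(grid$centers - nm))
  if (abs(grid$centers[i] - nm) > grid$step_nm) {
    stop(sprintf("wavelength %g nm is not on the grid", nm))
  }
  i
}
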