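#' Hyperspectral cube
#'
#' A hyperspectral line-scan cube is a 3-D array of non-negative
#' intensities or reflectances with dimensions (lines, cross-track pixels,
#' bands), together with its [wavelength_grid()].  `kind` distinguishes raw
#' camera counts (`"raw"`) from white/dark-calibrated relative reflectance
#' (`"reflectance"`).
#'
#' @param values numeric 3-D array, dimensions (lines, pixels, bands).
#' @param grid a [wavelength_grid()] whose length equals `dim(values)[3]`.
#' @param kind `"raw"` or `"reflectance"`.
#' @param metadata named list of free-form acquisition descriptors.
#'
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(values, grid, kind = c("raw", "reflectance"),
                      metadata = list()) {
  kind <- match.arg(kind)
  stopifnot(is.array(values), length(dim(values)) == 3,
            inherits(grid, "wavelength_grid"))
  if (dim(values)[3] != length(grid)) {
    stop(sprintf(
      "cube has %d bands but grid has %d", dim(values)[3], length(grid)
    ))
  }
  if (any(!is.finite(values))) {
    stop("cube values must be finite")
  }
  structure(
    list(values = values, grid = grid, kind = kind, metadata = metadata),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<hypercube> %s, %d lines x %d pixels x %d bands (%g-%g nm)\n",
    x$kind, d[1], d[2], d[3], x$grid$start_nm, x$grid$stop_nm
  ))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' White and dark reference frames
#'
#' Calibration references for a line-scan acquisition.  Each reference is
#' either a single line frame, a (pixels x bands) matrix broadcast along
#' the scan axis, or a full (lines x pixels x bands) cube.  The white
#' standard must exceed the dark current almost everywhere.
#'
#' @param white numeric matrix (pixels x bands) or 3-D array of
#'   white-standard intensities.
#' @param dark same-shaped dark-current intensities.
#' @param min_positive_frac minimum fraction of entries where
#'   `white > dark` (default 0.99).
#' @return An object of class `reference_frame`.
#' @export
reference_frame <- function(white, dark, min_positive_frac = 0.99) {
  stopifnot(is.numeric(white), is.numeric(dark))
  if (!identical(dim(white), dim(dark))) {
    stop("white and dark references must have identical shape")
  }
  if (all(white == 0)) {
    stop("all-zero white reference frame")
  }
  frac <- mean(white > dark)
  if (frac < min_positive_frac) {
    stop(sprintf(
      "white exceeds dark on only %.1f%% of entries (need >= %.1f%%)",
      100 * frac, 100 * min_positive_frac
    ))
  }
  structure(list(white = white, dark = dark), class = "reference_frame")
}

# expand a (pixels x bands) line reference to the cube's (lines) axis;
# full cubes pass through, after a shape check
.expand_reference <- function(ref, d) {
  if (is.matrix(ref)) {
    if (!identical(dim(ref), d[2:3])) {
      stop("line reference shape does not match cube (pixels x bands)")
    }
    aperm(array(ref, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  } else {
    if (!identical(dim(ref), d)) {
      stop("reference cube shape does not match sample cube")
    }
    ref
  }
}

#' Calibrate raw counts to relative reflectance
#'
#' Converts raw camera counts to relative reflectance using the standard
#' white/dark correction: for every pixel and band,
#' \deqn{I = (I_s - D) / (I_w - D)}
#' where \eqn{I_s} are the sample counts, \eqn{I_w} the white-standard
#' counts and \eqn{D} the dark current.  Denominators smaller in magnitude
#' than `epsilon` (dead pixels) are replaced by `epsilon` with the sign
#' preserved, and the result is clipped to `[0, clip_max]` so specular
#' glints cannot destabilise downstream preprocessing.
#'
#' @param raw a raw-kind [hypercube()].
#' @param refs a [reference_frame()]; line frames are broadcast along the
#'   scan axis.
#' @param epsilon floor for the white-minus-dark denominator, in count
#'   units (default `1e-6`).
#' @param clip_max ceiling for the calibrated reflectance (default 2).
#' @return A reflectance-kind [hypercube()] with the same dimensions.
#' @examples
#' g <- wavelength_grid(400, 404, 2)
#' raw <- hypercube(array(0.5, c(2, 2, 2)), g, "raw")
#' refs <- reference_frame(matrix(0.9, 2, 2), matrix(0.1, 2, 2))
#' calibrate_reflectance(raw, refs)$values[1, 1, 1]  # 0.5
#' @export
calibrate_reflectance <- function(raw, refs, epsilon = 1e-6, clip_max = 2) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_frame"))
  if (raw$kind != "raw") {
    stop("`raw` must be a raw-kind cube")
  }
  d <- dim(raw$values)
  w <- .expand_reference(refs$white, d)
  dk <- .expand_reference(refs$dark, d)
  denom <- w - dk
  small <- abs(denom) < epsilon
  if (any(small)) {
    denom[small] <- epsilon * ifelse(denom[small] < 0, -1, 1)
  }
  refl <- (raw$values - dk) / denom
  refl[refl < 0] <- 0
  refl[refl > clip_max] <- clip_max
  hypercube(refl, raw$grid, "reflectance",
            metadata = c(raw$metadata, list(calibrated = TRUE)))
}

#' Crop a cube spatially
#'
#' @param cube a [hypercube()].
#' @param lines,pixels integer index vectors into the two spatial axes.
#' @return The cropped [hypercube()].
#' @export
crop_cube <- function(cube, lines, pixels) {
  stopifnot(inherits(cube, "hypercube"))
  hypercube(cube$values[lines, pixels, , drop = FALSE], cube$grid,
            cube$kind, cube$metadata)
}
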