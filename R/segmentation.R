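#' Segment fruit from background by single-band thresholding
#'
#' In the VNIR range fruit is far brighter than a dark scanning stage, so
#' one well-chosen band separates the two: the mask keeps pixels whose
#' reflectance at the band nearest `band_nm` is at least `threshold`,
#' then retains only the largest 4-connected component, which removes
#' speckle and reflections off the stage.  Defaults (800 nm, reflectance
#' 0.2) suit citrus against a matte black background.
#'
#' @param cube a reflectance-kind [hypercube()].
#' @param band_nm wavelength (nm) of the thresholding band.
#' @param threshold reflectance cutoff.
#' @param min_pixels minimum size of the retained component (default 50).
#' @return An object of class `pixel_mask`: logical (lines x pixels)
#'   matrix `values` plus `source_band_nm` and `threshold`.
#' @export
segment_threshold <- function(cube, band_nm = 800, threshold = 0.2,
                              min_pixels = 50) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") {
    stop("segmentation requires a reflectance-kind cube")
  }
  band <- band_index(cube$grid, band_nm)
  plane <- cube$values[, , band]
  mask <- plane >= threshold
  if (!any(mask)) {
    stop(sprintf(
      "empty mask: no pixel >= %.3g at %g nm (max observed reflectance %.3g)",
      threshold, band_nm, max(plane)
    ))
  }
  labels <- EBImage::bwlabel(mask)
  sizes <- tabulate(labels[labels > 0])
  keep <- which.max(sizes)
  if (sizes[keep] < min_pixels) {
    stop(sprintf(
      "largest component has %d pixels (< min_pixels = %d) at threshold %.3g, band %g nm",
      sizes[keep], min_pixels, threshold, band_nm
    ))
  }
  structure(
    list(values = labels == keep, source_band_nm = band_nm,
         threshold = threshold),
    class = "pixel_mask"
  )
}

#' Mean spectrum over a region of interest
#'
#' Reduces one segmented sample to a single spectrum: the per-band
#' arithmetic mean of the reflectance over the masked pixels.
#'
#' @param cube a [hypercube()].
#' @param mask a `pixel_mask` from [segment_threshold()], or a logical
#'   (lines x pixels) matrix.
#' @return Numeric vector of length `bands`, named by band center.
#' @export
mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  m <- if (inherits(mask, "pixel_mask")) mask$values else mask
  stopifnot(is.logical(m))
  d <- dim(cube$values)
  if (!identical(dim(m), d[1:2])) {
    stop("mask shape does not match the cube's spatial dimensions")
  }
  if (!any(m)) {
    stop("mask selects no pixels")
  }
  flat <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  out <- colMeans(flat[as.vector(m), , drop = FALSE])
  names(out) <- paste0("R_", format(cube$grid$centers, trim = TRUE))
  out
}
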