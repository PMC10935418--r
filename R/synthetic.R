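#' Citrus-like spectrum template
#'
#' Parametric model of a citrus VNIR reflectance spectrum used by the
#' synthetic-data generator: a smooth baseline (logistic rise from the
#' blue through the red edge, then a gentle near-infrared decline)
#' minus a sum of Gaussian absorption features.  Each feature has a base
#' depth at the reference SSC and a linear SSC sensitivity
#' (Beer-Lambert small-absorbance approximation): feature depth is
#' `depth + sens * (ssc - ssc_ref)`.  The default features sit at the
#' wavelengths where citrus spectra show structure -- pigment absorptions
#' near 470, 640 and 680 nm, water/carbohydrate bands near 880 and
#' 960 nm with a reflectance shoulder at 912 nm -- with the SSC
#' sensitivity concentrated in the 912/960 nm O-H overtone region, so
#' the sugar signal lives above 800 nm.
#'
#' Per-sample scatter is modelled as a multiplicative gain
#' `1 + N(0, gain_sd)` and an additive offset `N(0, offset_sd)`;
#' measurement noise as i.i.d. `N(0, noise_sd)` per band.  The pigment
#' features additionally vary from sample to sample -- absorption depth
#' jitter (`depth_sd`) and band-position jitter (`shift_sd`, nm) --
#' emulating chlorophyll and carotenoid heterogeneity between fruits
#' that carries no sugar information.  This is the structured visible-band
#' nuisance that makes effective-wavelength selection worthwhile: the
#' NIR sugar/water bands are stable, the pigment bands are not.
#' `pigment_variability` scales both jitter columns; 0 disables them,
#' leaving exactly three latent variance directions (gain, offset, SSC
#' signal).
#'
#' @param features data frame with columns `center` (nm), `width`
#'   (Gaussian sd, nm), `depth` (reflectance units at `ssc_ref`), `sens`
#'   (depth change per degree Brix), and optionally `depth_sd`
#'   (per-sample depth jitter sd) and `shift_sd` (per-sample center
#'   jitter sd, nm; both default 0).
#' @param gain_sd sd of the multiplicative scatter gain (default 0.03).
#' @param offset_sd sd of the additive scatter offset (default 0.01).
#' @param noise_sd sd of per-band additive noise (default 0.02).
#' @param pigment_variability scale factor on the default pigment jitter
#'   (default 1; 0 turns pigment variation off).
#' @param ssc_ref reference SSC (degrees Brix) at which `depth` applies
#'   (default 9.85).
#' @return An object of class `spectrum_template`.
#' @export
citrus_template <- function(features = NULL, gain_sd = 0.03,
                            offset_sd = 0.01, noise_sd = 0.02,
                            pigment_variability = 1, ssc_ref = 9.85) {
  if (is.null(features)) {
    features <- data.frame(
      center = c(470, 640, 680, 880, 912, 960),
      width  = c(18, 30, 10, 16, 10, 22),
      depth  = c(0.07, 0.06, 0.035, 0.07, 0.02, 0.10),
      sens   = c(0.002, 0.002, 0.001, 0.003, 0.006, 0.012),
      depth_sd = pigment_variability * c(0.02, 0.02, 0.012, 0, 0, 0),
      shift_sd = pigment_variability * c(4, 4, 3, 0, 0, 0)
    )
  }
  if (is.null(features$depth_sd)) features$depth_sd <- 0
  if (is.null(features$shift_sd)) features$shift_sd <- 0
  stopifnot(all(c("center", "width", "depth", "sens") %in% names(features)),
            all(features$width > 0), all(features$depth > 0),
            all(features$depth_sd >= 0), all(features$shift_sd >= 0),
            gain_sd >= 0, offset_sd >= 0, noise_sd >= 0)
  structure(
    list(features = features, gain_sd = gain_sd, offset_sd = offset_sd,
         noise_sd = noise_sd, ssc_ref = ssc_ref),
    class = "spectrum_template"
  )
}

# smooth baseline: logistic rise to the red edge, gentle NIR decline
.template_baseline <- function(lambda) {
  0.15 + 0.60 * stats::plogis((lambda - 570) / 55) -
    0.12 * stats::plogis((lambda - 880) / 60)
}

#' Noise-free template spectrum at a given SSC
#'
#' @param template a [citrus_template()].
#' @param grid a [wavelength_grid()].
#' @param ssc soluble solid content (degrees Brix).
#' @return Reflectance vector over the grid.
#' @export
template_spectrum <- function(template, grid, ssc) {
  stopifnot(inherits(template, "spectrum_template"),
            inherits(grid, "wavelength_grid"))
  lam <- grid$centers
  f <- template$features
  if (any(f$center < grid$start_nm | f$center > grid$stop_nm)) {
    stop("template feature centers must lie within the grid")
  }
  out <- .template_baseline(lam)
  for (j in seq_len(nrow(f))) {
    depth <- f$depth[j] + f$sens[j] * (ssc - template$ssc_ref)
    out <- out - depth * exp(-(lam - f$center[j])^2 / (2 * f$width[j]^2))
  }
  out
}

#' SSC sensitivity vector of a template
#'
#' The derivative of the noise-free spectrum with respect to SSC: a
#' fixed vector (the SSC-depth relation is linear) whose norm sets how
#' much spectral signal one degree Brix produces.
#'
#' @inheritParams template_spectrum
#' @return Numeric vector over the grid (reflectance per degree Brix,
#'   negative where absorption deepens with SSC).
#' @export
ssc_sensitivity <- function(template, grid) {
  lam <- grid$centers
  f <- template$features
  g <- numeric(length(lam))
  for (j in seq_len(nrow(f))) {
    g <- g - f$sens[j] * exp(-(lam - f$center[j])^2 / (2 * f$width[j]^2))
  }
  g
}

#' Noise-equivalent SSC floor of a template
#'
#' The best root-mean-square SSC error any unbiased spectral predictor
#' can reach on data from [generate_spectra_dataset()]: per-band noise of
#' sd `noise_sd` projected onto the SSC signal direction.  Nuisance
#' variation a calibration must null -- the scatter axes (flat offset
#' and mean-spectrum gain) and, to first order, the pigment jitter axes
#' (each varying feature's Gaussian for depth jitter and its derivative
#' for position jitter) -- spans a subspace the signal is first
#' orthogonalized against; overlap with those axes raises the floor.
#'
#' @inheritParams template_spectrum
#' @param noise_sd per-band noise sd; default: the template's.
#' @return SSC error floor (degrees Brix).
#' @export
ssc_noise_floor <- function(template, grid, noise_sd = template$noise_sd) {
  g <- ssc_sensitivity(template, grid)
  lam <- grid$centers
  f <- template$features
  nuisance <- NULL
  if (template$gain_sd > 0 || template$offset_sd > 0) {
    nuisance <- cbind(1, template_spectrum(template, grid, template$ssc_ref))
  }
  for (j in seq_len(nrow(f))) {
    gauss <- exp(-(lam - f$center[j])^2 / (2 * f$width[j]^2))
    if (f$depth_sd[j] > 0) nuisance <- cbind(nuisance, gauss)
    if (f$shift_sd[j] > 0) {
      nuisance <- cbind(nuisance, gauss * (lam - f$center[j]) / f$width[j]^2)
    }
  }
  if (!is.null(nuisance)) {
    g <- stats::lsfit(nuisance, g, intercept = FALSE)$residuals
  }
  noise_sd / sqrt(sum(g^2))
}

#' Truncated-normal SSC distribution
#'
#' Defaults describe the pooled SSC of a 324-fruit citrus harvest:
#' mean 9.85, sd 1.08, range 7.40-12.50 degrees Brix.
#'
#' @param mean,sd,min,max distribution parameters (degrees Brix).
#' @return An object of class `ssc_distribution`.
#' @export
ssc_distribution <- function(mean = 9.85, sd = 1.08, min = 7.40,
                             max = 12.50) {
  stopifnot(min < max, sd > 0, mean > min, mean < max)
  structure(list(mean = mean, sd = sd, min = min, max = max),
            class = "ssc_distribution")
}

# truncated-normal draws by rejection
.draw_ssc <- function(n, dist) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, dist$mean, dist$sd)
    out <- c(out, x[x >= dist$min & x <= dist$max])
  }
  out[seq_len(n)]
}

#' Generate a synthetic citrus spectra dataset
#'
#' Draws one SSC per fruit from the truncated-normal distribution, then
#' for each orientation builds the noise-free template spectrum at that
#' SSC and applies per-sample multiplicative gain, additive offset and
#' per-band noise.  The two orientation spectra of a fruit share the SSC
#' but have independent scatter and noise, emulating two scans of the
#' same fruit.  The returned table carries the generator's
#' noise-equivalent SSC floor (attribute `ssc_noise_floor`) so recovery
#' tests can compare achieved errors against the attainable one.
#'
#' @param n_fruits number of fruits (default 324, giving 648 spectra at
#'   two orientations).
#' @param orientations scans per fruit (default 2).
#' @param template a [citrus_template()].
#' @param ssc_dist an [ssc_distribution()].
#' @param grid a [wavelength_grid()] (default 400-1000 nm at 2 nm).
#' @param seed RNG seed.
#' @return A [spectra_table()] with attributes `ssc_noise_floor`,
#'   `noise_sd` and `template`.
#' @export
generate_spectra_dataset <- function(n_fruits = 324, orientations = 2,
                                     template = citrus_template(),
                                     ssc_dist = ssc_distribution(),
                                     grid = wavelength_grid(),
                                     seed = NULL) {
  stopifnot(n_fruits >= 1, orientations >= 1)
  if (!is.null(seed)) set.seed(seed)
  # reject templates that can go negative anywhere in the SSC range
  worst <- template_spectrum(template, grid, ssc_dist$max)
  if (any(worst < 0)) {
    stop("template produces negative noise-free reflectance at high SSC")
  }
  ssc_fruit <- .draw_ssc(n_fruits, ssc_dist)
  n <- n_fruits * orientations
  p <- length(grid)
  X <- matrix(0, n, p)
  fruit_id <- rep(seq_len(n_fruits), each = orientations)
  orientation <- rep(letters[seq_len(orientations)], times = n_fruits)
  ssc <- ssc_fruit[fruit_id]
  lam <- grid$centers
  f <- template$features
  base <- .template_baseline(lam)
  for (i in seq_len(n)) {
    clean <- base
    for (j in seq_len(nrow(f))) {
      depth <- f$depth[j] + f$sens[j] * (ssc[i] - template$ssc_ref) +
        stats::rnorm(1, 0, f$depth_sd[j])
      center <- f$center[j] + stats::rnorm(1, 0, f$shift_sd[j])
      clean <- clean - depth * exp(-(lam - center)^2 / (2 * f$width[j]^2))
    }
    gain <- 1 + stats::rnorm(1, 0, template$gain_sd)
    offset <- stats::rnorm(1, 0, template$offset_sd)
    X[i, ] <- gain * clean + offset + stats::rnorm(p, 0, template$noise_sd)
  }
  out <- spectra_table(X, ssc, grid$centers, fruit_id = fruit_id,
                       orientation = orientation)
  attr(out, "ssc_noise_floor") <- ssc_noise_floor(template, grid)
  attr(out, "noise_sd") <- template$noise_sd
  attr(out, "template") <- template
  out
}

#' Generate a synthetic raw cube with matching references
#'
#' Builds a line-scan scene containing one circular fruit of the given
#' SSC on a flat dark background, converts the intended reflectance to
#' raw counts against supplied white/dark levels, and returns the raw
#' cube together with consistent reference frames -- so
#' [calibrate_reflectance()] followed by [segment_threshold()] and
#' [mean_spectrum()] recovers the template spectrum up to noise.
#'
#' @param fruit_radius_px disk radius in pixels (>= 1).
#' @param scene_dims `c(lines, pixels)` of the scene; the disk must fit.
#' @param template a [citrus_template()].
#' @param ssc fruit SSC (degrees Brix).
#' @param background_reflectance background level (default 0.05).
#' @param grid a [wavelength_grid()].
#' @param white_level,dark_level reference count levels (defaults 3000
#'   and 100, a 12-bit-camera scale).
#' @param noise_sd per-band noise in reflectance units applied to the
#'   raw counts (default: the template's).
#' @param seed RNG seed.
#' @return List with `cube` (raw [hypercube()]), `refs`
#'   ([reference_frame()]), `mask` (logical disk), and `spectrum` (the
#'   noise-free template spectrum inside the disk).
#' @export
generate_cube <- function(fruit_radius_px, scene_dims = c(60, 60),
                          template = citrus_template(), ssc = 9.85,
                          background_reflectance = 0.05,
                          grid = wavelength_grid(),
                          white_level = 3000, dark_level = 100,
                          noise_sd = template$noise_sd, seed = NULL) {
  if (fruit_radius_px < 1) stop("fruit radius must be at least 1 pixel")
  nl <- scene_dims[1]
  np <- scene_dims[2]
  cl <- (nl + 1) / 2
  cp <- (np + 1) / 2
  if (fruit_radius_px > min(cl, cp) - 1) {
    stop("disk does not fit in the scene")
  }
  if (!is.null(seed)) set.seed(seed)
  spec <- template_spectrum(template, grid, ssc)
  if (any(spec < 0)) stop("template produces negative reflectance")
  p <- length(grid)
  mask <- outer(seq_len(nl), seq_len(np),
                function(r, c) (r - cl)^2 + (c - cp)^2 <= fruit_radius_px^2)
  refl <- array(background_reflectance, dim = c(nl, np, p))
  for (b in seq_len(p)) {
    plane <- refl[, , b]
    plane[mask] <- spec[b]
    refl[, , b] <- plane
  }
  white <- matrix(white_level, np, p)
  dark <- matrix(dark_level, np, p)
  raw <- refl * (white_level - dark_level) + dark_level
  if (noise_sd > 0) {
    raw <- raw + array(stats::rnorm(length(raw), 0,
                                    noise_sd * (white_level - dark_level)),
                       dim = dim(raw))
  }
  list(
    cube = hypercube(raw, grid, "raw"),
    refs = reference_frame(white, dark),
    mask = mask,
    spectrum = spec
  )
}

#' Plant reference-value outliers in a spectra table
#'
#' Shifts the SSC reference of randomly chosen samples by
#' `shift_sd_multiples` noise-equivalent standard deviations (random
#' sign), emulating mis-measured reference values, and returns the
#' planted indices so a detector's recall can be scored.
#'
#' @param table a [spectra_table()].
#' @param n_outliers number of samples to contaminate
#'   (< `n / 10`; default 17).
#' @param shift_sd_multiples shift magnitude in units of `noise_sd`
#'   (positive; default 5).
#' @param noise_sd the noise-equivalent SSC sd (degrees Brix); defaults
#'   to the table's `ssc_noise_floor` attribute.
#' @param seed RNG seed.
#' @return List with `table` (contaminated copy) and `planted` (sorted
#'   indices).
#' @export
inject_outliers <- function(table, n_outliers = 17, shift_sd_multiples = 5,
                            noise_sd = attr(table, "ssc_noise_floor"),
                            seed = NULL) {
  stopifnot(inherits(table, "spectra_table"))
  n <- nrow(table$X)
  if (n_outliers >= n / 10) {
    stop("n_outliers must be below a tenth of the sample count")
  }
  if (shift_sd_multiples <= 0) {
    stop("a zero shift does not make an outlier")
  }
  if (is.null(noise_sd)) {
    stop("noise_sd missing: supply it or use a generated table")
  }
  if (!is.null(seed)) set.seed(seed)
  planted <- sort(sample(n, n_outliers))
  shift <- shift_sd_multiples * noise_sd *
    sample(c(-1, 1), n_outliers, replace = TRUE)
  table$ssc[planted] <- table$ssc[planted] + shift
  list(table = table, planted = planted)
}
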