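# shared fixtures built in code

# tiny grid for cube tests: 10 bands, 400-420 nm
tiny_grid <- function() wavelength_grid(400, 420, 2)

# flat-spectrum cube of constant reflectance
constant_cube <- function(value, lines = 6, pixels = 6,
                          grid = tiny_grid()) {
  hypercube(array(value, c(lines, pixels, length(grid))), grid,
            "reflectance")
}

# deterministic template: no scatter, no noise, no pigment jitter
clean_template <- function(noise_sd = 0) {
  citrus_template(gain_sd = 0, offset_sd = 0, noise_sd = noise_sd,
                  pigment_variability = 0)
}

# ordinary least-squares predictions (normal equations), the oracle for
# full-rank PLSR
ols_predictions <- function(X, y, X_new = X) {
  Z <- cbind(1, X)
  beta <- solve(crossprod(Z), crossprod(Z, y))
  drop(cbind(1, X_new) %*% beta)
}

# planted-signal regression data for CARS: y depends on a handful of
# named bands only
planted_band_data <- function(n = 80, p = 120,
                              informative = c(10, 30, 55, 80, 100),
                              noise = 0.3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  coefs <- c(1, -1, 1, 1, -1)[seq_along(informative)]
  y <- drop(X[, informative] %*% coefs) + rnorm(n, 0, noise) + 10
  list(table = spectra_table(X, y, seq_len(p)), informative = informative)
}
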