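Package: carspls
Title: CARS-PLSR Chemometrics for Hyperspectral Prediction of Fruit
    Soluble Solids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting soluble solid content (SSC, degrees
    Brix) of citrus fruit from visible/near-infrared (400-1000 nm)
    hyperspectral reflectance images.  Provides white/dark reference
    calibration and ENVI-style cube input/output, threshold segmentation
    and region-of-interest mean spectra, the standard chemometric
    preprocessing transforms (moving average, Savitzky-Golay first
    derivative, maximum/mean/range normalization, standard normal
    variate, multiplicative scatter correction), single-response partial
    least-squares regression (NIPALS) with leave-one-out and k-fold
    cross-validated factor selection, competitive adaptive reweighted
    sampling (CARS) for effective-wavelength selection, Monte Carlo
    prediction-error outlier screening, and an end-to-end model
    comparison pipeline.  A synthetic citrus-spectra generator with
    known soluble-solid signal, scatter and planted outliers makes every
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
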