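---
title: "Methods: hyperspectral SSC calibration with CARS-PLSR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral SSC calibration with CARS-PLSR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures in `carspls`, the
assumptions behind them, the defaults and why they were chosen, and
what the synthetic-data generator does and does not emulate. It is the
design record of the package; no numbers are claimed here that the test
suite and `scripts/acceptance.R` do not themselves compute.

## From cube to spectrum

A line-scan VNIR acquisition yields a raw-count cube indexed
(line, pixel, band) on a uniform wavelength grid — by default 400–1000
nm at 2 nm, i.e. 300 bands under the half-open convention
`[start, stop)`. Raw counts are converted to relative reflectance
band-by-band against a white diffuse-reflectance standard and a
shutter-closed dark frame:

$$I = \frac{I_s - D}{I_w - D}$$

Two numerical guards are applied, neither of which an idealized
description needs but real (or simulated dead-pixel) data does:

* denominators with `|I_w − D| < epsilon` (default `1e-6`) are replaced
  by `epsilon`, sign preserved, so dead reference pixels cannot produce
  non-finite reflectance;
* output is clipped to `[0, clip_max]` (default 2.0): specular glints
  exceed 1 and unbounded values destabilize preprocessing.

References may be a single line frame (pixels × bands), broadcast along
the scan axis — the line-scan convention, and the default produced by
the simulator — or full cubes. Calibration is element-wise, so it
commutes with spatial cropping; the tests assert this exactly.

Fruit is separated from background by thresholding a single band
(default 800 nm, where fruit is bright and a matte stage is dark, at
reflectance 0.2; both configurable since no universal values exist),
keeping only the largest 4-connected component (speckle and stage
reflections are smaller than the fruit). The ROI is the whole
segmented fruit, and each scan is reduced to the per-band arithmetic
mean over ROI pixels. Cubes are stored in the ENVI convention (ASCII
header + flat binary, BIL default); integral raw counts are written as
16-bit integers (sufficient for a 12-bit sensor), everything else as
32-bit floats.

## Preprocessing

Seven row-wise transforms are provided: moving average, Savitzky–Golay
first derivative, maximum/mean/range normalization, SNV and MSC.
Choices needing justification:

* **Window.** The smoothing/derivative gap is given in nm. A "6 nm
  gap" is ambiguous between a half-width (7 points at 2 nm: center ± 3
  bands) and a total width (3 points); the package defaults to the
  half-width reading (`gap_mode = "half_width"`) because a 3-point
  quadratic Savitzky–Golay window is degenerate, and exposes
  `gap_mode = "total_width"` for the narrower reading. Moving-average
  ends shrink the window to the in-range part; the derivative uses the
  edge-window polynomial fits, which keeps it exact on polynomials up
  to the fit order over the *whole* spectrum.
* **Derivative units** are reflectance per nm (divided by the grid
  step), so results are resolution-independent. Polynomial order
  defaults to 2.
* **SNV** uses the n−1 standard deviation (chemometrics convention).
* **MSC** regresses each spectrum on a reference by OLS and corrects
  `(x − a)/b`. The reference is the column mean of the data the
  preprocessor was *fitted* on, then frozen: in the pipeline it is
  learned from calibration rows and reused unchanged for prediction
  rows. Slopes below `1e-12` in magnitude are rejected rather than
  divided by.

Only MSC learns anything from data; all other transforms are strictly
per-spectrum, which is why the batch-equals-rowwise property holds for
them exactly.

## PLSR

Single-response NIPALS with mean centering and X-only deflation; with
one response the inner iteration converges in a single step, so no
iteration loop (or tolerance for it) is needed. Factor extraction
stops early when the residual covariance or score variance falls below
`1e-12` of its initial scale, and the achieved factor count is
recorded. The model carries collapsed regression coefficients for
*every* factor count `1..F` via `R = W (P'W)^{-1}`, so cross-validation
and prediction at any factor count are single matrix products.

Cross-validation is implemented on centered cross-product matrices
(the kernel form of PLS1): each held-out fold downdates `X'X` and
`X'y` rather than refitting from the data matrix, making a full
leave-one-out sweep over 20 factor counts on a 454 × 300 calibration
set a matter of seconds. The kernel and NIPALS routes are verified
against each other to machine precision in the tests, and full-rank
PLSR is verified against an ordinary least-squares oracle.

Other conventions:

* `R²` is defined as `1 − SSres/SStot` about the evaluation set's own
  mean (not a squared correlation), making `RMSE² = (1 − R²)·var(y)`
  an exact identity the tests assert.
* The 7:3 split rounds the calibration share half away from zero
  (648 → 454/194, 631 → 442/189, 10 → 7/3). Orientation replicates of
  one fruit may land on opposite sides by default; `group_by_fruit =
  TRUE` gives the leakage-safe alternative at the cost of approximate
  split sizes.
* The cross-validated factor count is the RMSECV argmin with ties —
  up to a relative `1e-8`, or `1e-10·sd(y)` absolute for the exactly
  fitted case — broken toward fewer factors. The factor cap is 20.
* The reported `R2_v`/`RMSEV` are computed from the held-out LOOCV
  predictions at the selected factor count; no separate validation
  subset is held out, since the workflow defines only calibration and
  prediction sets.

## CARS

Each of `N = 100` Monte Carlo runs: (1) fit a PLS model on a random
80% of calibration samples restricted to the retained bands, with the
factor count chosen by 5-fold CV on that subset, capped at
`min(10, bands − 1)` (subsets shrink far below the global cap of 20);
(2) enforced selection keeps the `round(r_i·p)` bands of largest
absolute coefficient, with `r_i = a·e^{−k·i}` calibrated so `r_1 = 1`
and `r_N = 2/p`; (3) adaptive reweighted sampling draws `round(r_i·p)`
bands with replacement, weight proportional to `|b|`, and keeps the
unique draws — so the realized subset can be smaller than the enforced
size, which is stated explicitly because implementations differ;
(4) the RMSECV of the surviving subset on the full calibration set is
recorded. The subset minimizing RMSECV is selected.

Two further choices matter in practice:

* **Paired folds.** The step-4 RMSECV uses one 5-fold assignment drawn
  at the start of the run and reused for every iteration. Reshuffling
  folds each iteration adds noise of several percent to the
  trajectory, which swamps the genuine differences between subsets and
  drags the argmin toward the (earliest, largest) subsets; with paired
  folds the trajectory is a paired comparison.
* **Tie-break.** The argmin takes the earliest iteration (the larger,
  safer subset); an all-zero coefficient vector falls back to uniform
  weights with a warning; if the retained set collapses below 2 bands
  the sequence is truncated and recorded.

The sampling fraction (0.8), the internal CV scheme (5-fold), and the
internal factor cap are not prescribed by the workflow this package
implements; they are the conventional choices in the CARS literature
and are exposed as arguments.

## Monte Carlo outlier screening

`n_runs = 500` random 75/25 train/test splits; each records every test
sample's absolute prediction error under a PLS fit with a *fixed*
factor count (selected once by LOOCV on the full table before the
runs — re-selecting factors per run would confound the error
distributions). A sample is flagged when its error mean or error sd
exceeds the population mean of that statistic plus `k_sigma = 2.5`
population sds. Flagging uses the OR of the two cutoffs: high bias and
high variance both disqualify. Cutoffs are floored at `1e-8·sd(y)` so
exactly-fitted data (errors at rounding level) flags nothing. Samples
appearing in the test portion fewer than 20 times trigger automatic
run extension. Removal happens on the full table, before the 7:3
split and before CARS, so both model variants of a comparison see the
same cleaned data.

The defaults were chosen so that planted-outlier recall in the
acceptance simulation (17 contaminated references among 648, shifted
by ±5 noise-equivalent sds) is high at a small false-flag rate; the
tests quantify both.

## The synthetic generator

The generator is the package's study stand-in; all its data are
synthetic and labelled as such. It emulates:

* **Spectral shape.** A smooth baseline (logistic rise from ~0.17 at
  400 nm through the red edge, gentle NIR decline) minus Gaussian
  absorption features at 470, 640, 680, 880, 912 and 960 nm — pigment
  bands in the visible, water/carbohydrate bands in the NIR, with a
  reflectance shoulder at 912 nm between the two NIR absorptions.
* **Sugar signal.** Feature depth is linear in SSC (Beer–Lambert
  small-absorbance rationale), with sensitivity concentrated at
  912/960 nm (0.006 and 0.012 reflectance units per °Brix) and an
  order of magnitude weaker in the visible. No quantitative SSC-depth
  calibration exists to copy, so the sensitivities are a generator
  choice, pinned here, sized so the default noise level leaves a
  noise-equivalent floor of about 0.4 °Brix (reported exactly by
  `ssc_noise_floor()`).
* **SSC distribution.** Truncated normal, mean 9.85, sd 1.08, range
  7.40–12.50 °Brix, drawn per fruit by rejection sampling; two
  orientations per fruit share the SSC but get independent scatter and
  noise. Harvest-stage structure is emulated only through the pooled
  distribution.
* **Scatter and noise.** Per-sample multiplicative gain (sd 0.03) and
  additive offset (sd 0.01), i.i.d. per-band noise (sd 0.02) —
  magnitudes typical of diffuse-reflectance fruit measurements.
* **Pigment variability.** Per-sample jitter of the visible features'
  depths (sd 0.02/0.02/0.012) and center positions (sd 4/4/3 nm),
  emulating chlorophyll/carotenoid heterogeneity between fruits that
  carries no sugar information. Position jitter is *nonlinear* in the
  spectrum, so no small set of latent factors can null it completely —
  which is precisely what makes the visible bands worth discarding and
  gives wavelength selection something real to find. Setting
  `pigment_variability = 0` leaves exactly three latent variance
  directions (signal, gain, offset), the configuration used to test
  latent-rank recovery.
* **Outliers.** Contamination is modelled as reference-value errors:
  chosen samples' SSC shifted by ±5 noise-equivalent sds.

The **noise floor** is the key honesty device: per-band noise
projected onto the SSC sensitivity vector after orthogonalizing it
against the nuisance axes the calibration must null (offset, gain, and
the first-order pigment-jitter directions). Prediction RMSE is judged
against this attainable bound rather than against an arbitrary number.

What the generator does **not** emulate: radiative-transfer realism,
peel-thickness effects, orientation-dependent spectral differences
(orientations are replicate noise), correlated instrument drift, and
harvest-stage mean structure. Consequently, passing tests demonstrate
that the estimators recover what was planted under the stated noise
model — not that any particular accuracy will be reached on real fruit.

## Pipeline staging and leakage

Stage order per variant: optional outlier removal on the full table
(screening uses spectra preprocessed on the full table), then the 7:3
split (shared across variants of one preprocessing method, so
comparisons are paired), then preprocessing refitted on calibration
rows and applied frozen to prediction rows, then optional CARS on the
calibration set only, then LOOCV factor selection, final fit, and
evaluation. Only MSC actually learns anything at the preprocessing
stage, but the refit-on-calibration rule is applied uniformly; a test
perturbs the prediction rows and asserts the fitted model is
byte-identical. Outlier screening intentionally sees the full table:
it is a data-quality filter, not part of the predictive model, and the
631-sample split after removal implies removal precedes splitting.
Screening runs once per preprocessing method and is shared by the two
outlier-removing variants.

All randomness descends from one base seed through fixed per-stage
offsets, so a config plus seed reproduces every artifact byte for
byte.

## Problem sizes used in the checks

The test suite and acceptance script run at the study's native scale
where that is cheap — 648 spectra × 300 bands for the pipeline,
outlier, and CARS checks (the kernel cross-validation makes full LOOCV
on 454 × 300 a few seconds) — and at reduced scale where many seeds
are needed: latent-rank recovery uses 160 spectra × 300 bands over 10
seeds, planted-band recovery 80 × 120 over 10 seeds, and the
pure-noise selection null 90 × 50. These sizes are the package's
choices for statistically meaningful yet quick checks.

## Known limitations

* PLS1 only; no multi-response PLS2, kernel PLS, or interval PLS.
* Segmentation assumes one fruit per scene on a dark background; no
  touching-fruit separation or stem/calyx landmarking.
* The ENVI reader supports uniform wavelength grids and data types
  2/4/5 (int16/float32/float64) only.
* CARS results are seed-dependent by construction; one seeded run is
  the default, and stability across seeds is characterized, not
  eliminated.
* The generator's sensitivities are synthetic; absolute accuracies
  measured on it do not transfer to any instrument.
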