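#' Gaussian absorption band
#'
#' A species' molar absorptivity is modelled as a Gaussian in wavelength
#' whose area equals the species' integral extinction coefficient, so band
#' integration of a synthetic spectrum recovers the generating coefficients.
#'
#' @param center Band center (nm).
#' @param width Gaussian sigma (nm), positive.
#' @param integral_eps Band area = the species' integral extinction
#'   coefficient (AU nm / M / cm), non-negative.
#' @return An object of class `band_shape`.
#' @export
band_shape <- function(center, width, integral_eps) {
  if (width <= 0) stopf("band width must be positive")
  if (integral_eps < 0) stopf("integral_eps must be >= 0")
  structure(list(center = center, width = width, integral_eps = integral_eps),
            class = "band_shape")
}

#' Synthetic-data scenario
#'
#' Bundles an aggregation model, the monomer and aggregate band shapes
#' (whose areas must realize the model's extinction coefficients), a
#' concentration grid, the integration window and the noise level.
#'
#' @param model An [aggregation_model()].
#' @param monomer_band,aggregate_band [band_shape()]s; their `integral_eps`
#'   must equal `model$eps1` and `model$epsn`.
#' @param conc_grid Total concentrations (mol/L), positive ascending.
#' @param window A [band_window()] for the integration.
#' @param noise_rel Relative sd of the multiplicative Gaussian noise
#'   (default 0.01). Applied per wavelength point by [generate_spectra()]
#'   and directly to the integral absorbance by [generate_curve()].
#' @param seed Optional integer seed for reproducible noise.
#' @param conc_noise_rel Optional relative error on the prepared
#'   concentrations (speciation uses the perturbed values while the labels
#'   keep the nominal ones); 0 by default.
#' @param wavelength_grid Wavelength axis (nm) for spectral realization;
#'   default: 1-nm grid extending 60 nm beyond the window.
#' @return An object of class `dye_scenario`.
#' @export
dye_scenario <- function(model, monomer_band, aggregate_band, conc_grid,
                         window, noise_rel = 0.01, seed = NULL,
                         conc_noise_rel = 0, wavelength_grid = NULL) {
  stopifnot(inherits(model, "aggregation_model"),
            inherits(monomer_band, "band_shape"),
            inherits(aggregate_band, "band_shape"),
            inherits(window, "band_window"))
  if (abs(monomer_band$integral_eps - model$eps1) > 1e-9 * max(model$eps1, 1))
    stopf("monomer band area (%g) must equal the model's eps1 (%g)",
          monomer_band$integral_eps, model$eps1)
  if (abs(aggregate_band$integral_eps - model$epsn) > 1e-9 * max(model$epsn, 1))
    stopf("aggregate band area (%g) must equal the model's epsn (%g)",
          aggregate_band$integral_eps, model$epsn)
  conc_grid <- as.numeric(conc_grid)
  if (any(conc_grid <= 0) || any(diff(conc_grid) <= 0))
    stopf("conc_grid must be positive and strictly ascending")
  if (is.null(wavelength_grid))
    wavelength_grid <- seq(max(0, window$lambda_lo - 60),
                           window$lambda_hi + 60, by = 1)
  structure(list(model = model, monomer_band = monomer_band,
                 aggregate_band = aggregate_band, conc_grid = conc_grid,
                 window = window, noise_rel = noise_rel, seed = seed,
                 conc_noise_rel = conc_noise_rel,
                 wavelength_grid = as.numeric(wavelength_grid)),
            class = "dye_scenario")
}

#' Scenario presets emulating the three studied dye systems
#'
#' * `"fs_upw"`: sodium fluorescein in water; trimer, `K = 1.4e9` M^-2,
#'   monomer band at 486 nm, `eps1 = 0.241 > epsn = 0.027` (concave
#'   absorbance curve), 24-point geometric grid over 0.518-133 uM,
#'   window \[390, 552\] nm.
#' * `"fs_acn"`: fluorescein in acetonitrile; trimer, `K = 6.3e6` M^-2,
#'   `eps1 = 0.04 < epsn = 0.389` (convex), grid 20-133 uM, same window.
#'   The monomer coefficient is a stand-in: only "small" is known.
#' * `"mb_upw"`: methylene blue in water; tetramer, `K = 1.15e13` M^-3,
#'   monomer band at 661 nm, aggregate band at 615 nm, grid 6-44 uM,
#'   window \[500, 800\] nm. The extinction pair (1.0, 0.25) is a stand-in;
#'   recovery of K is insensitive to it.
#'
#' Band widths are stand-ins chosen so the windows capture more than four
#' sigma of every band.
#'
#' @param name One of `"fs_upw"`, `"fs_acn"`, `"mb_upw"`.
#' @param noise_rel Relative noise level (default 0.01).
#' @param seed Optional seed.
#' @return A [dye_scenario()].
#' @export
dye_preset <- function(name, noise_rel = 0.01, seed = NULL) {
  presets <- c("fs_upw", "fs_acn", "mb_upw")
  if (!is.character(name) || length(name) != 1 || !(name %in% presets))
    stopf("unknown preset '%s'; available: %s",
          paste(name, collapse = ","), paste(presets, collapse = ", "))
  switch(name,
    fs_upw = dye_scenario(
      model = aggregation_model(3, 1.4e9, 0.241, 0.027, 1),
      monomer_band = band_shape(486, 15, 0.241),
      aggregate_band = band_shape(486, 16.5, 0.027),
      conc_grid = geom_grid(0.518e-6, 133e-6, 24),
      window = band_window(390, 552),
      noise_rel = noise_rel, seed = seed,
      wavelength_grid = seq(250, 650, by = 1)),
    fs_acn = dye_scenario(
      model = aggregation_model(3, 6.3e6, 0.04, 0.389, 1),
      monomer_band = band_shape(486, 15, 0.04),
      aggregate_band = band_shape(486, 18, 0.389),
      conc_grid = geom_grid(20e-6, 133e-6, 24),
      window = band_window(390, 552),
      noise_rel = noise_rel, seed = seed,
      wavelength_grid = seq(250, 600, by = 1)),
    mb_upw = dye_scenario(
      model = aggregation_model(4, 1.15e13, 1.0, 0.25, 1),
      monomer_band = band_shape(661, 18, 1.0),
      aggregate_band = band_shape(615, 22, 0.25),
      conc_grid = geom_grid(6e-6, 44e-6, 24),
      window = band_window(500, 800),
      noise_rel = noise_rel, seed = seed,
      wavelength_grid = seq(400, 800, by = 1)))
}

## Concentrations actually realized in the cuvettes: nominal grid, optionally
## perturbed by the preparation error.
realized_concentrations <- function(scenario) {
  C <- scenario$conc_grid
  if (scenario$conc_noise_rel > 0)
    C <- C * (1 + stats::rnorm(length(C), 0, scenario$conc_noise_rel))
  C
}

#' Generate a synthetic spectral series
#'
#' For each concentration the equilibrium is speciated and the spectrum
#' assembled as \eqn{A(\lambda) = \ell [C_1 g_1(\lambda) + n C_n
#' g_n(\lambda)]}, with \eqn{g_i} Gaussian bands scaled so their area equals
#' the species' integral extinction coefficient. Multiplicative Gaussian
#' noise of sd `noise_rel` is applied independently per wavelength point
#' (photometric noise scales with signal); band integration therefore
#' averages it down by roughly the square root of the band width in grid
#' points. Reproducible under the scenario's seed.
#'
#' @param scenario A [dye_scenario()].
#' @return A [spectral_series()].
#' @export
generate_spectra <- function(scenario) {
  stopifnot(inherits(scenario, "dye_scenario"))
  wl <- scenario$wavelength_grid
  spacing <- min(diff(wl))
  if (min(scenario$monomer_band$width, scenario$aggregate_band$width) <
      10 * spacing)
    warnf("wavelength grid too coarse: fewer than 10 points per band sigma")
  g1 <- scenario$monomer_band$integral_eps *
    stats::dnorm(wl, scenario$monomer_band$center, scenario$monomer_band$width)
  gn <- scenario$aggregate_band$integral_eps *
    stats::dnorm(wl, scenario$aggregate_band$center, scenario$aggregate_band$width)
  build <- function() {
    C <- realized_concentrations(scenario)
    sp <- speciate(scenario$model, C)
    l <- scenario$model$path_length
    spectra <- lapply(seq_along(C), function(i) {
      A <- l * (sp$C1[i] * g1 + scenario$model$n * sp$Cn[i] * gn)
      if (scenario$noise_rel > 0)
        A <- A * (1 + stats::rnorm(length(A), 0, scenario$noise_rel))
      dye_spectrum(wl, A, label = sprintf("synthetic C=%.4g M", C[i]))
    })
    spectral_series(spectra, scenario$conc_grid, l)
  }
  if (is.null(scenario$seed)) build() else withr::with_seed(scenario$seed, build())
}

#' Generate a synthetic absorbance curve directly
#'
#' Shortcut skipping the spectral realization: the integral absorbance is
#' computed from the forward model and the multiplicative noise applied to
#' it directly. Note the different effective noise level compared with
#' [generate_spectra()], where per-wavelength noise is averaged down by the
#' band integration.
#'
#' @param scenario A [dye_scenario()].
#' @return An [absorbance_curve()].
#' @export
generate_curve <- function(scenario) {
  stopifnot(inherits(scenario, "dye_scenario"))
  build <- function() {
    C <- realized_concentrations(scenario)
    A <- predict_integral_absorbance(scenario$model, C)
    if (scenario$noise_rel > 0)
      A <- A * (1 + stats::rnorm(length(A), 0, scenario$noise_rel))
    absorbance_curve(scenario$conc_grid, A, scenario$model$path_length,
                     scenario$window)
  }
  if (is.null(scenario$seed)) build() else withr::with_seed(scenario$seed, build())
}
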