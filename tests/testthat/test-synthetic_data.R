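test_that("presets encode the three study systems", {
  fs <- dye_preset("fs_upw")
  expect_equal(fs$model$n, 3L)
  expect_equal(fs$model$K_n, 1.4e9)
  expect_equal(c(fs$window$lambda_lo, fs$window$lambda_hi), c(390, 552))
  expect_gt(fs$model$eps1, fs$model$epsn)
  expect_equal(range(fs$conc_grid), c(0.518e-6, 133e-6))

  acn <- dye_preset("fs_acn")
  expect_equal(acn$model$n, 3L)
  expect_lt(acn$model$eps1, acn$model$epsn)
  expect_equal(range(acn$conc_grid), c(20e-6, 133e-6))

  mb <- dye_preset("mb_upw")
  expect_equal(mb$model$n, 4L)
  expect_equal(mb$model$K_n, 1.15e13)
  expect_equal(mb$monomer_band$center, 661)
  expect_equal(mb$aggregate_band$center, 615)
  expect_equal(range(mb$conc_grid), c(6e-6, 44e-6))

  expect_error(dye_preset("nope"), "fs_upw, fs_acn, mb_upw")
})

test_that("generation is reproducible under a fixed seed", {
  sc <- dye_preset("fs_upw", seed = 123)
  s1 <- generate_spectra(sc)
  s2 <- generate_spectra(sc)
  expect_identical(s1, s2)
  expect_identical(generate_curve(sc), generate_curve(sc))
  # different seed, different noise
  sc2 <- dye_preset("fs_upw", seed = 124)
  expect_false(identical(generate_curve(sc2), generate_curve(sc)))
})

test_that("band areas realize the generating extinction coefficients", {
  # single species visible: kill aggregation so the spectrum is pure monomer
  m <- aggregation_model(3, 1e-30, 0.8, 0.2, 1)
  sc <- dye_scenario(m, band_shape(500, 12, 0.8), band_shape(540, 12, 0.2),
                     conc_grid = c(1e-5, 2e-5), window = band_window(440, 560),
                     noise_rel = 0, wavelength_grid = seq(380, 680, 1))
  ser <- generate_spectra(sc)
  a <- integrate_band(ser$spectra[[1]], band_window(500 - 60, 500 + 60))
  expect_equal(a, 0.8 * 1e-5, tolerance = 1e-3)  # +-5 sigma captures the band

  # two species: the full window reproduces the model's prediction
  m2 <- aggregation_model(3, 1e9, 0.8, 0.2, 1)
  sc2 <- dye_scenario(m2, band_shape(500, 12, 0.8), band_shape(540, 12, 0.2),
                      conc_grid = c(1e-5, 5e-5, 1e-4),
                      window = band_window(400, 660),
                      noise_rel = 0, wavelength_grid = seq(380, 680, 1))
  cv <- to_absorbance_curve(generate_spectra(sc2), sc2$window)
  expect_equal(cv$integral_absorbance,
               predict_integral_absorbance(m2, sc2$conc_grid),
               tolerance = 1e-3)
})

test_that("generator speciation obeys the equilibrium law at every grid point", {
  for (p in c("fs_upw", "fs_acn", "mb_upw")) {
    sc <- dye_preset(p)
    sp <- speciate(sc$model, sc$conc_grid)
    expect_equal(sp$Cn / sp$C1^sc$model$n,
                 rep(sc$model$K_n, length(sc$conc_grid)), tolerance = 1e-8)
  }
})

test_that("noiseless curvature matches the sign of eps1 - epsn", {
  for (p in c("fs_upw", "fs_acn", "mb_upw")) {
    sc <- dye_preset(p, noise_rel = 0)
    cv <- generate_curve(sc)
    raw <- cv$integral_absorbance -
      sc$model$eps1 * sc$model$path_length * cv$concentrations
    expected <- if (sc$model$eps1 > sc$model$epsn) -1 else 1
    expect_true(all(sign(raw) == expected))
  }
})

test_that("curve shortcut agrees with the band-realized spectra", {
  for (p in c("fs_upw", "mb_upw")) {
    sc <- dye_preset(p, noise_rel = 0)
    cv_direct <- generate_curve(sc)
    cv_band <- to_absorbance_curve(generate_spectra(sc), sc$window)
    expect_equal(cv_band$integral_absorbance, cv_direct$integral_absorbance,
                 tolerance = 0.01)
    expect_length(cv_direct$integral_absorbance, length(sc$conc_grid))
  }
})

test_that("no-aggregation scenario produces a straight Lambert-Beer line", {
  m <- aggregation_model(3, 1e-30, 0.5, 0.1, 2)
  sc <- dye_scenario(m, band_shape(500, 12, 0.5), band_shape(540, 12, 0.1),
                     conc_grid = c(1e-6, 1e-5, 1e-4),
                     window = band_window(440, 560), noise_rel = 0)
  cv <- generate_curve(sc)
  expect_equal(cv$integral_absorbance, 0.5 * 2 * sc$conc_grid,
               tolerance = 1e-10)
})

test_that("noiseless presets are exactly identifiable end-to-end", {
  for (p in c("fs_upw", "fs_acn", "mb_upw")) {
    sc <- dye_preset(p, noise_rel = 0)
    fit <- fit_aggregation(generate_spectra(sc), window = sc$window)
    expect_equal(fit$model$n, sc$model$n)
    expect_equal(fit$model$K_n, sc$model$K_n, tolerance = 1e-3)
    expect_equal(fit$model$epsn, sc$model$epsn, tolerance = 1e-3)
  }
})

test_that("scenario validation rejects inconsistent bands and coarse grids", {
  m <- aggregation_model(3, 1e9, 0.8, 0.2, 1)
  expect_error(dye_scenario(m, band_shape(500, 12, 0.7), band_shape(540, 12, 0.2),
                            conc_grid = 1e-5, window = band_window(440, 560)),
               "monomer band area")
  sc <- dye_scenario(m, band_shape(500, 2, 0.8), band_shape(540, 12, 0.2),
                     conc_grid = 1e-5, window = band_window(440, 560),
                     noise_rel = 0, wavelength_grid = seq(400, 600, 1))
  expect_warning(generate_spectra(sc), "too coarse")
})
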