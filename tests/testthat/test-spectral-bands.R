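test_that("band evaluates to its amplitude at the peak and half of it at FWHM", {
  b <- skewed_gaussian_band(nu_max_cm1 = 1e7 / 540, amplitude = 0.5,
                            width_cm1 = 3000, skew = 0)
  expect_equal(evaluate_band(b, 540), 0.5)
  # symmetric limit: half maximum exactly at nu_max +/- width/2
  nus <- b$nu_max_cm1 + c(-1, 1) * b$width_cm1 / 2
  expect_equal(evaluate_band(b, 1e7 / nus), c(0.25, 0.25))
})

test_that("skewed band matches the closed-form value (frozen oracle)", {
  # independent direct evaluation of the Fraser-Suzuki expression at 500 nm
  b <- skewed_gaussian_band(18519, 1.0, 4000, 0.3)
  expect_equal(evaluate_band(b, 500), 0.733481846277, tolerance = 1e-10)
})

test_that("band is non-negative and exactly zero outside its support", {
  b <- skewed_gaussian_band(18519, 1.0, 4000, 0.5)
  wl <- seq(300, 900, 1)
  v <- evaluate_band(b, wl)
  expect_true(all(v >= 0))
  # support edge: 1 + 2 s (nu - nu0)/w <= 0  <=>  nu <= nu0 - w/(2 s)
  nu_edge <- b$nu_max_cm1 - b$width_cm1 / (2 * b$skew)
  outside <- 1e7 / wl < nu_edge
  expect_true(any(outside))
  expect_true(all(v[outside] == 0))
})

test_that("skew -> 0 converges to the symmetric Gaussian", {
  wl <- seq(400, 710, 2)
  g <- skewed_gaussian_band(18519, 0.8, 3500, 0)
  s <- skewed_gaussian_band(18519, 0.8, 3500, 1e-6)
  expect_lt(max(abs(evaluate_band(s, wl) - evaluate_band(g, wl))),
            1e-6 * 0.8)
})

test_that("band mode stays at nu_max across skews (dense-grid argmax)", {
  nu_grid <- seq(14000, 26000, 1)
  for (sk in c(-0.5, -0.2, 0.2, 0.5)) {
    b <- skewed_gaussian_band(18519, 1, 3500, sk)
    v <- evaluate_band(b, 1e7 / nu_grid)
    i <- which.max(v)
    expect_lt(abs(nu_grid[i] - 18519), 1.5, # within one 1 cm-1 step
              label = sprintf("argmax offset at skew %g", sk))
  }
})

test_that("invalid band parameters and wavelengths are rejected", {
  expect_error(skewed_gaussian_band(18519, 1, -100), class = "rhodofit_invalid")
  expect_error(skewed_gaussian_band(18519, -1, 100), class = "rhodofit_invalid")
  b <- skewed_gaussian_band(18519, 1, 3500, 0)
  expect_error(evaluate_band(b, c(500, -10)), class = "rhodofit_invalid")
  expect_error(band_at_lambda(-540, 1, 3500), class = "rhodofit_invalid")
})

test_that("noiseless single-band decomposition recovers the generating band", {
  truth <- band_at_lambda(540, 0.5, 3400, 0.25)
  wl <- seq(400, 710, 5)
  spec <- absorption_spectrum(wl, evaluate_band(truth, wl))
  fit <- fit_bands(spec, 1, baseline = FALSE)
  b <- fit$bands[[1]]
  expect_lt(rel_err(b$nu_max_cm1, truth$nu_max_cm1), 1e-5)
  expect_lt(rel_err(b$amplitude, truth$amplitude), 1e-5)
  expect_lt(rel_err(b$width_cm1, truth$width_cm1), 1e-4)
  expect_lt(abs(b$skew - truth$skew), 1e-4)
  expect_lt(fit$residual_sd, 1e-8)
})

test_that("band position survives a Rayleigh scattering baseline", {
  truth <- band_at_lambda(540, 0.5, 3400, 0.2)
  wl <- seq(400, 710, 5)
  # baseline ~10% of peak at the band maximum
  base_coeff <- 0.1 * 0.5 * (540 / 550)^4
  y <- evaluate_band(truth, wl) + base_coeff * (wl / 550)^-4
  fit <- fit_bands(absorption_spectrum(wl, y), 1, baseline = TRUE, seed = 11)
  expect_lt(abs(1e7 / fit$bands[[1]]$nu_max_cm1 - 540), 1)
  expect_lt(rel_err(fit$baseline_coeff, base_coeff), 0.2)
})

test_that("two-band decomposition round-trips positions within 0.5%", {
  main <- band_at_lambda(540, 0.5, 3400, 0.2)
  beta <- band_at_lambda(400, 0.075, 3500, 0.2)
  wl <- seq(360, 710, 5)
  spec <- absorption_spectrum(wl, evaluate_band(main, wl) + evaluate_band(beta, wl))
  fit <- fit_bands(spec, 2, init = list(band_at_lambda(550, 0.4, 3000, 0.1),
                                        band_at_lambda(410, 0.1, 3000, 0.1)),
                   baseline = FALSE, window = c(360, 710))
  # bands come back sorted by wavenumber descending: beta first
  expect_lt(rel_err(fit$bands[[1]]$nu_max_cm1, beta$nu_max_cm1), 0.005)
  expect_lt(rel_err(fit$bands[[2]]$nu_max_cm1, main$nu_max_cm1), 0.005)
})

test_that("n_bands = 0 is a precondition violation", {
  wl <- seq(400, 710, 10)
  spec <- absorption_spectrum(wl, exp(-((wl - 540) / 50)^2))
  expect_error(fit_bands(spec, 0), class = "rhodofit_invalid")
})

test_that("refined lambda_max stays within one grid step of the grid maximum", {
  truth <- band_at_lambda(543.7, 0.5, 3500, 0.2)
  wl <- seq(400, 710, 10)
  spec <- absorption_spectrum(wl, evaluate_band(truth, wl))
  lm_grid <- lambda_max(spec, refined = FALSE)
  lm_ref <- lambda_max(spec)
  expect_lte(abs(lm_ref - lm_grid), 10)
  expect_lt(abs(lm_ref - 543.7), 2)  # refinement beats the 10-nm grid
})

test_that("pigment model evaluation is the sum of its parts", {
  m <- pigment_spectrum_model(band_at_lambda(540, 0.5, 3500, 0.2),
                              band_at_lambda(400, 0.075, 3500, 0.2),
                              baseline_coeff = 0.01)
  wl <- seq(400, 710, 10)
  v <- evaluate_pigment_model(m, wl)
  expect_true(all(v >= 0))
  expect_equal(v, evaluate_band(m$main_band, wl) + evaluate_band(m$beta_band, wl) +
                 0.01 * (wl / 550)^-4)
})
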