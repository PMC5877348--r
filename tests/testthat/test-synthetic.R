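test_that("scenario defaults equal the emulated study conditions", {
  sc <- rmhr_scenario()
  expect_equal(sc$tau_ms, c(0.105, 0.483, 2.14, 23.5))
  expect_equal(sc$state_lambda_max_nm$P1, 510)
  expect_equal(sc$state_lambda_max_nm$P2, 510)
  expect_equal(sc$state_lambda_max_nm$P3, c(N = 520, O = 590))
  expect_equal(sc$state_lambda_max_nm$P4, 540)
  expect_equal(sc$lambda_max_unbound_nm, 550)
  expect_equal(sc$lambda_max_unbound_nm + sc$lambda_max_shift_nm, 542)
  expect_equal(sc$kd_int_mM, 7.6)
  expect_equal(sc$hill_n, 1.2)
  expect_equal(sc$kd_rel_mM, 308)
  expect_equal(sc$pka_low_salt, 7.3)
  expect_equal(sc$pka_high_salt, 10)
})

test_that("generators are deterministic given scenario and seed", {
  sc <- rmhr_scenario()
  expect_identical(make_titration(sc, "lambda_max", seed = 4)$y,
                   make_titration(sc, "lambda_max", seed = 4)$y)
  expect_identical(make_flash_dataset(sc, seed = 4)$dataset$delta_abs,
                   make_flash_dataset(sc, seed = 4)$dataset$delta_abs)
  a <- make_p3_series(sc, seed = 4)$series[[1]]$spectrum$absorbance
  b <- make_p3_series(sc, seed = 4)$series[[1]]$spectrum$absorbance
  expect_identical(a, b)
  expect_false(identical(make_titration(sc, "lambda_max", seed = 4)$y,
                         make_titration(sc, "lambda_max", seed = 5)$y))
})

test_that("flash dataset uses the standard measurement grids", {
  sim <- make_flash_dataset(rmhr_scenario(), seed = 1)
  expect_equal(sim$dataset$wavelengths_nm, seq(400, 710, 10))
  expect_length(sim$dataset$wavelengths_nm, 32)
  expect_gte(min(sim$dataset$times_s), 1e-5)
  expect_lte(max(sim$dataset$times_s), 0.388)
})

test_that("noiseless titration endpoints match the forward model", {
  sc <- rmhr_scenario()
  curve <- make_titration(sc, "lambda_max", n_points = 12, noise_sd = 0)
  # exact Hill values at the span endpoints (1 mM and 4 M)
  expect_equal(curve$y[1], 549.3549363, tolerance = 1e-7)
  expect_lt(abs(curve$y[1] - 550), 0.7)
  expect_lt(abs(curve$y[12] - 542.0043387), 0.1)
  tr <- attr(curve, "truth")
  expect_equal(tr$Kd, 7.6)
  # ionic-strength bookkeeping: Na2SO4 balance recorded, never fitted
  meta <- attr(curve, "metadata")
  expect_equal(meta$na2so4_mM, pmax(0, (4000 - curve$x) / 3))
  expect_lte(max(meta$na2so4_mM), 1333.1)
})

test_that("N-like fraction increases with chloride", {
  curve <- make_titration(rmhr_scenario(), "fraction_N", n_points = 8,
                          span = c(100, 4000), noise_sd = 0)
  expect_true(all(diff(curve$y) > 0))
  expect_lt(curve$y[1], curve$y[8])
})

test_that("earliest flash column is close to the first difference spectrum", {
  sim <- make_flash_dataset(rmhr_scenario(), noise_sd = 0)
  d1 <- sim$truth$state_delta_spectra[1, ]
  col1 <- sim$dataset$delta_abs[, 1]
  # at 10 us about 9% of P1 has already moved on (tau1 = 0.105 ms)
  expect_lt(max(abs(col1 - d1)) / max(abs(d1)), 0.15)
  P <- state_populations(sim$truth$tau_ms, sim$dataset$times_s[1])
  pred <- as.numeric(t(sim$truth$state_delta_spectra) %*% P)
  expect_equal(col1, pred, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("chloride concentration changes only the mixture state's truth", {
  sc <- rmhr_scenario()
  lo <- make_flash_dataset(sc, cl_mM = 100, noise_sd = 0)
  hi <- make_flash_dataset(sc, cl_mM = 4000, noise_sd = 0)
  expect_gt(hi$f_N, lo$f_N)
  wl <- lo$dataset$wavelengths_nm
  # P3 difference spectra shift weight from 590 to 520 nm with chloride
  expect_gt(max(abs(hi$truth$state_delta_spectra[3, ] -
                    lo$truth$state_delta_spectra[3, ])), 0.01)
  # P1 state is chloride-independent apart from the shared P0 reference
  p0_lo <- evaluate_band(lo$p0_model$main_band, wl)
  p0_hi <- evaluate_band(hi$p0_model$main_band, wl)
  expect_lt(max(abs((lo$truth$state_delta_spectra[1, ] + p0_lo) -
                    (hi$truth$state_delta_spectra[1, ] + p0_hi))), 1e-12)
})

test_that("P3 series is dominated by the expected band at the extremes", {
  sc <- rmhr_scenario()
  ser <- make_p3_series(sc, concentrations_mM = c(10, 4000), noise_sd = 0)
  lm_lo <- lambda_max(ser$series[[1]]$spectrum, window = c(450, 710))
  lm_hi <- lambda_max(ser$series[[2]]$spectrum, window = c(450, 710))
  expect_gt(lm_lo, 570)   # far below Kd_rel: O-like (590 nm) dominates
  expect_lt(lm_hi, 545)   # far above: N-like (520 nm) dominates
})

test_that("generator domain errors", {
  sc <- rmhr_scenario()
  expect_error(make_titration(sc, "lambda_max", span = c(0, 4000)),
               class = "rhodofit_domain")
  expect_error(make_titration(sc, "lambda_max", span = c(1, 5000)),
               class = "rhodofit_domain")
  expect_error(make_p3_series(sc, concentrations_mM = numeric(0)),
               class = "rhodofit_domain")
  expect_error(make_p3_series(sc, concentrations_mM = c(100, 4500)),
               class = "rhodofit_domain")
  expect_error(make_flash_dataset(sc, cl_mM = NULL),
               class = "rhodofit_configuration")
})

test_that("end-to-end synthetic series round-trips the release constant", {
  sc <- rmhr_scenario()
  ser <- make_p3_series(sc, seed = 52)
  fit <- fit_shared_bands(ser, beta = ser$beta)
  rel <- release_constant(fit$fractions, kd_int_mM = sc$kd_int_mM)
  expect_lt(rel_err(rel$Kd, sc$kd_rel_mM), 0.15)
})
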