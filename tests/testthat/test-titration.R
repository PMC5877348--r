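test_that("Hill model has the right limits and half-saturation point", {
  expect_equal(hill_eval(550, -8, 7.6, 1.2, 0), 550)
  expect_equal(hill_eval(550, -8, 7.6, 1.2, 7.6), 550 - 4)     # a + b/2 at Kd
  expect_equal(hill_eval(2, 3, 5, 0.7, 5), 2 + 1.5)
  # frozen direct-evaluation oracle at the titration endpoint
  expect_equal(hill_eval(550, -8, 7.6, 1.2, 4000), 542.0043387,
               tolerance = 1e-9)
  expect_error(hill_eval(550, -8, 7.6, 1.2, -1), class = "rhodofit_domain")
  expect_error(hill_eval(550, -8, -2, 1.2, 10), class = "rhodofit_invalid")
})

test_that("noiseless Hill fit is self-consistent to 1e-6 relative", {
  x <- 10^seq(0, log10(4000), length.out = 12)
  curve <- titration_curve(x, hill_eval(550, -8, 7.6, 1.2, x), "lambda_max")
  fit <- fit_hill(curve)
  expect_lt(rel_err(fit$a, 550), 1e-6)
  expect_lt(rel_err(fit$b, -8), 1e-6)
  expect_lt(rel_err(fit$Kd, 7.6), 1e-6)
  expect_lt(rel_err(fit$n, 1.2), 1e-6)
})

test_that("reparameterized (mirrored) data give identical Kd and n", {
  sc <- rmhr_scenario()
  curve <- make_titration(sc, "lambda_max", n_points = 12, seed = 18)
  mirrored <- titration_curve(curve$x, (550 + (-8)) - curve$y + 550,
                              "lambda_max")
  f1 <- fit_hill(curve)
  # polish both fits from the (mapped) optimum: the mirrored objective is an
  # exact reflection, so the two optima must coincide
  f1 <- fit_hill(curve, init = list(a = f1$a, b = f1$b, Kd = f1$Kd, n = f1$n))
  f2 <- fit_hill(mirrored, init = list(a = 1092 - f1$a, b = -f1$b,
                                       Kd = f1$Kd, n = f1$n))
  expect_lt(rel_err(f2$Kd, f1$Kd), 1e-8)
  expect_lt(rel_err(f2$n, f1$n), 1e-8)
})

test_that("uptake-constant recovery is unbiased at the measurement design", {
  # 12 log-spaced points, 0.3 nm noise: the sampling SD of Kd-hat is about
  # 1.2 mM, so the median relative error sits near 12%; assert the
  # design-supported bound
  sc <- rmhr_scenario()
  errs <- vapply(1:50, function(s) {
    fit <- fit_hill(make_titration(sc, "lambda_max", n_points = 12, seed = s))
    rel_err(fit$Kd, sc$kd_int_mM)
  }, 0)
  expect_lt(stats::median(errs), 0.15)
})

test_that("fraction-kind curve generated at the release constant recovers it", {
  sc <- rmhr_scenario()
  curve <- make_titration(sc, "fraction_N", n_points = 10,
                          span = c(100, 4000), seed = 6)
  fit <- fit_hill(curve)
  expect_lt(rel_err(fit$Kd, 308), 0.15)
})

test_that("a flat curve raises a no-transition error", {
  x <- 10^seq(0, 3, length.out = 8)
  set.seed(2)
  curve <- titration_curve(x, 550 + rnorm(8, 0, 0.05), "lambda_max")
  expect_error(fit_hill(curve), class = "rhodofit_no_transition")
})

test_that("pKa fit recovers the midpoint identity exactly when noiseless", {
  pH <- seq(5, 10, length.out = 10)
  y <- 1 / (1 + 10^(7.3 - pH))
  fit <- fit_pka(titration_curve(pH, y, "deltaA_380"))
  expect_lt(abs(fit$pKa - 7.3), 1e-8)
  # fitted curve crosses half its amplitude scale exactly at pKa
  at_pka <- fit$amplitude_scale / (1 + 10^(fit$pKa - fit$pKa))
  expect_lt(abs(at_pka - fit$amplitude_scale / 2), 1e-9)
})

test_that("pKa recovery within 0.1 pH unit at design noise", {
  sc <- rmhr_scenario()
  errs <- vapply(1:20, function(s) {
    curve <- make_titration(sc, "deltaA_380", n_points = 10, seed = 300 + s)
    abs(fit_pka(curve)$pKa - sc$pka_low_salt)
  }, 0)
  expect_lt(stats::median(errs), 0.05)
  expect_lt(max(errs), 0.15)
})

test_that("decreasing deltaA against pH violates the sign convention", {
  pH <- seq(5, 10, length.out = 8)
  y <- 1 - 1 / (1 + 10^(7.3 - pH))
  expect_error(fit_pka(titration_curve(pH, y, "deltaA_380")),
               class = "rhodofit_sign_convention")
})

test_that("a pH range missing the transition is flagged as poorly constrained", {
  pH <- seq(8.5, 10, length.out = 6)
  y <- 1 / (1 + 10^(5.5 - pH))        # transition far below the window
  expect_warning(fit_pka(titration_curve(pH, y, "deltaA_380")),
                 class = "rhodofit_poorly_constrained")
})

test_that("release constant: noiseless joint N/O fit is exact with fold-ratio", {
  x <- 10^seq(2, log10(4000), length.out = 8)
  fN <- hill_eval(0, 1, 308, 1.2, x)
  ft <- data.frame(conc_mM = x, f_N = fN, f_O = 1 - fN)
  fit <- release_constant(ft, kd_int_mM = 7.6)
  expect_lt(rel_err(fit$Kd, 308), 1e-6)
  expect_lt(rel_err(fit$n, 1.2), 1e-6)
  expect_equal(fit$fold_ratio, fit$Kd / 7.6)
  expect_lt(abs(fit$fold_ratio - 308 / 7.6), 1e-3)
})

test_that("release constant validates complementarity and range", {
  x <- 10^seq(2, log10(4000), length.out = 6)
  fN <- hill_eval(0, 1, 308, 1.2, x)
  bad_sum <- data.frame(conc_mM = x, f_N = fN, f_O = 1 - fN + 0.01)
  expect_error(release_constant(bad_sum), class = "rhodofit_invalid")
  bad_range <- data.frame(conc_mM = x, f_N = fN * 1.4, f_O = 1 - fN * 1.4)
  expect_error(release_constant(bad_range), class = "rhodofit_invalid")
})

test_that("titration curve validates its inputs", {
  expect_error(titration_curve(c(1, 10, 100), c(1, 2, 3), "lambda_max"),
               class = "rhodofit_invalid")              # too few points
  expect_error(titration_curve(c(-1, 1, 10, 100), 1:4, "lambda_max"),
               class = "rhodofit_invalid")              # negative conc
  expect_silent(titration_curve(seq(5, 10, 1), seq(0, 1, 0.2), "deltaA_380"))
})
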