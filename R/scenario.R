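#' Ground-truth scenario for a marine-bacterial chloride-pump rhodopsin
#'
#' Bundles the generating parameters used by every synthetic-data
#' generator: the four photocycle time constants of the sequential model,
#' the absorption maxima of the kinetic states (the third state being an
#' N/O quasi-equilibrium mixture), the Cl- titration of the
#' unphotolyzed-state absorption maximum (550 nm unbound shifting by -8 nm
#' to 542 nm at full saturation), the uptake and release dissociation
#' constants, the Hill coefficient, the Schiff-base pKa at low and high
#' salt, band-shape defaults and per-observable noise levels. Every field
#' can be overridden; generators return the truth alongside the data so
#' recovery tests never re-derive it.
#'
#' @param tau_ms Photocycle time constants (ms).
#' @param state_lambda_max_nm Named list of state absorption maxima (nm);
#'   `P3` is a length-2 vector `c(N =, O =)` of the mixture components.
#' @param lambda_max_unbound_nm,lambda_max_shift_nm Offset `a` and
#'   amplitude `b` of the unphotolyzed-state maximum titration
#'   (`a + b` = fully bound maximum).
#' @param kd_int_mM,hill_n Uptake dissociation constant and Hill
#'   coefficient of the initial state.
#' @param kd_rel_mM Release dissociation constant governing the N/O
#'   fraction.
#' @param pka_low_salt,pka_high_salt Schiff-base pKa at 0 M and 4 M NaCl.
#' @param peak_od Peak optical density of the sample main band.
#' @param band_width_cm1,band_skew Default main-band shape.
#' @param beta_nu_max_cm1,beta_rel_amplitude,beta_width_cm1 Beta-band
#'   position, amplitude relative to the main band, and width.
#' @param noise Named list of noise SDs: `lambda_max_nm`, `flash_dOD`,
#'   `spectrum_od`, `deltaA`, `fraction` (the last emulating the
#'   uncertainty of fractions obtained by spectral decomposition).
#' @param seed Default seed for the generators.
#' @return Object of class `rmhr_scenario` (a validated list).
#' @export
rmhr_scenario <- function(tau_ms = c(0.105, 0.483, 2.14, 23.5),
                          state_lambda_max_nm = list(
                            P1 = 510, P2 = 510,
                            P3 = c(N = 520, O = 590), P4 = 540),
                          lambda_max_unbound_nm = 550,
                          lambda_max_shift_nm = -8,
                          kd_int_mM = 7.6, hill_n = 1.2, kd_rel_mM = 308,
                          pka_low_salt = 7.3, pka_high_salt = 10,
                          peak_od = 0.5,
                          band_width_cm1 = 3500, band_skew = 0.2,
                          beta_nu_max_cm1 = 25000,
                          beta_rel_amplitude = 0.15,
                          beta_width_cm1 = 3500,
                          noise = list(lambda_max_nm = 0.3,
                                       flash_dOD = 5e-4,
                                       spectrum_od = 1e-3,
                                       deltaA = 0.02,
                                       fraction = 0.005),
                          seed = 1) {
  if (any(tau_ms <= 0) || any(diff(tau_ms) <= 0))
    rf_stop("tau_ms must be positive and strictly increasing", "invalid")
  if (kd_int_mM <= 0 || kd_rel_mM <= 0 || hill_n <= 0)
    rf_stop("dissociation constants and Hill coefficient must be positive",
            "invalid")
  structure(list(
    tau_ms = tau_ms, state_lambda_max_nm = state_lambda_max_nm,
    lambda_max_unbound_nm = lambda_max_unbound_nm,
    lambda_max_shift_nm = lambda_max_shift_nm,
    kd_int_mM = kd_int_mM, hill_n = hill_n, kd_rel_mM = kd_rel_mM,
    pka_low_salt = pka_low_salt, pka_high_salt = pka_high_salt,
    peak_od = peak_od, band_width_cm1 = band_width_cm1,
    band_skew = band_skew, beta_nu_max_cm1 = beta_nu_max_cm1,
    beta_rel_amplitude = beta_rel_amplitude,
    beta_width_cm1 = beta_width_cm1, noise = noise, seed = seed),
    class = "rmhr_scenario")
}

# Na2SO4 concentration (mM) balancing the ionic strength to 4 M:
# I(NaCl) = c, I(Na2SO4) = 3 c, so the balance is (4000 - cl) / 3.
na2so4_balance_mM <- function(cl_mM) pmax(0, (4000 - cl_mM) / 3)

# scenario helpers ----------------------------------------------------------

scenario_beta_band <- function(scenario) {
  skewed_gaussian_band(scenario$beta_nu_max_cm1,
                       scenario$beta_rel_amplitude * scenario$peak_od,
                       scenario$beta_width_cm1, scenario$band_skew)
}

scenario_main_band <- function(scenario, lambda_nm) {
  band_at_lambda(lambda_nm, scenario$peak_od, scenario$band_width_cm1,
                 scenario$band_skew)
}

# unphotolyzed-state absorption maximum at a Cl- concentration (noiseless)
scenario_p0_lambda <- function(scenario, cl_mM) {
  hill_eval(scenario$lambda_max_unbound_nm, scenario$lambda_max_shift_nm,
            scenario$kd_int_mM, scenario$hill_n, cl_mM)
}

# N-like fraction of the quasi-equilibrium state at a Cl- concentration
scenario_f_N <- function(scenario, cl_mM) {
  hill_eval(0, 1, scenario$kd_rel_mM, scenario$hill_n, cl_mM)
}

#' Generate a synthetic titration curve
#'
#' Forward-models one titration experiment and adds seeded Gaussian noise.
#' Kinds:
#' \describe{
#'   \item{`lambda_max`}{unphotolyzed-state absorption maximum (nm) vs
#'     \[Cl-\], Hill model `a + b h(c)` with the scenario's uptake
#'     constant; log-spaced concentrations over `span` (default
#'     1 mM - 4 M).}
#'   \item{`fraction_N` / `fraction_O`}{N-like (or O-like) fraction of the
#'     quasi-equilibrium state vs \[Cl-\], Hill model with the release
#'     constant.}
#'   \item{`deltaA_380`}{normalized 380-nm absorbance rise vs pH
#'     (Henderson-Hasselbalch with the scenario's low-salt pKa);
#'     `span` is then a pH range (default 5-10) on a linear grid.}
#' }
#' The attached `truth` records the generating parameters; for
#' concentration kinds the metadata also records the Na2SO4 concentration
#' balancing ionic strength at 4 M (bookkeeping only; sulfate is not a
#' substrate and enters no fit).
#'
#' @param scenario An [rmhr_scenario()].
#' @param kind Observable kind (see above).
#' @param n_points Number of points (>= 4).
#' @param span `c(min, max)`: mM for concentration kinds (within
#'   (0, 4000]), pH for `deltaA_380`.
#' @param noise_sd Noise SD; default from the scenario's noise table.
#' @param seed Seed (default from the scenario).
#' @return A [titration_curve()] with attributes `truth` (named list) and
#'   `metadata`.
#' @export
make_titration <- function(scenario, kind = c("lambda_max", "fraction_N",
                                              "fraction_O", "deltaA_380"),
                           n_points = 12, span = NULL, noise_sd = NULL,
                           seed = scenario$seed) {
  stopifnot(inherits(scenario, "rmhr_scenario"))
  kind <- match.arg(kind)
  if (!is_number(n_points) || n_points < 4)
    rf_stop("n_points must be >= 4", "invalid")
  if (kind == "deltaA_380") {
    if (is.null(span)) span <- c(5, 10)
    if (is.null(noise_sd)) noise_sd <- scenario$noise$deltaA
    x <- seq(span[1], span[2], length.out = n_points)
    y0 <- 1 / (1 + 10^(scenario$pka_low_salt - x))
    truth <- list(pKa = scenario$pka_low_salt, scale = 1)
    meta <- list(buffer = "6-mix", condition = "low salt")
  } else {
    if (is.null(span)) span <- c(1, 4000)
    if (span[1] <= 0 || span[2] > 4000 || span[2] <= span[1])
      rf_stop("concentration span must lie within (0, 4000] mM", "domain")
    x <- 10^seq(log10(span[1]), log10(span[2]), length.out = n_points)
    truth <- switch(kind,
      lambda_max = list(a = scenario$lambda_max_unbound_nm,
                        b = scenario$lambda_max_shift_nm,
                        Kd = scenario$kd_int_mM, n = scenario$hill_n),
      fraction_N = list(a = 0, b = 1, Kd = scenario$kd_rel_mM,
                        n = scenario$hill_n),
      fraction_O = list(a = 1, b = -1, Kd = scenario$kd_rel_mM,
                        n = scenario$hill_n))
    y0 <- hill_eval(truth$a, truth$b, truth$Kd, truth$n, x)
    # fraction observables emulate decomposition outputs, whose uncertainty
    # is spectral noise propagated through the linear fraction solution
    if (is.null(noise_sd))
      noise_sd <- if (kind == "lambda_max") scenario$noise$lambda_max_nm
                  else scenario$noise$fraction
    meta <- list(na2so4_mM = na2so4_balance_mM(x), ionic_strength_mM = 4000)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  y <- y0 + stats::rnorm(n_points, 0, noise_sd)
  out <- titration_curve(x, y, kind)
  attr(out, "truth") <- c(truth, list(noise_sd = noise_sd, seed = seed,
                                      y_noiseless = y0))
  attr(out, "metadata") <- meta
  out
}

#' Generate a synthetic flash-photolysis dataset with known truth
#'
#' Builds the absolute spectra of the four kinetic states as
#' skewed-Gaussian main bands at the scenario maxima (the third state
#' being the Cl--dependent f-weighted N/O mixture, with f given by the
#' release-constant Hill curve at `cl_mM`), forms the difference spectra
#' against the unphotolyzed state (whose maximum follows the uptake
#' titration at `cl_mM`), and simulates the measurement on the standard
#' 400-710 nm / 10-nm grid over 10 us - 388 ms. Difference spectra are
#' expressed per unit photolyzed population, so adding the
#' unphotolyzed-state spectrum to a difference spectrum recovers that
#' state's pure spectrum.
#'
#' @param scenario An [rmhr_scenario()].
#' @param cl_mM Cl- concentration of the emulated measurement (default
#'   1000 mM). Required because the mixture composition of the third state
#'   depends on it.
#' @param wavelengths_nm,times_s Measurement grids.
#' @param noise_sd Flash noise SD in delta-OD; default from the scenario.
#' @param seed Seed.
#' @return List of class `flash_simulation`: `dataset`
#'   ([flash_photolysis_dataset()]), `truth` ([sequential_photocycle()]
#'   including the P0 spectrum), `p0_model`
#'   ([pigment_spectrum_model()]), `f_N`, `cl_mM`, `state_lambda_max_nm`.
#' @export
make_flash_dataset <- function(scenario, cl_mM = 1000,
                               wavelengths_nm = seq(400, 710, 10),
                               times_s = flash_time_grid(),
                               noise_sd = scenario$noise$flash_dOD,
                               seed = scenario$seed) {
  stopifnot(inherits(scenario, "rmhr_scenario"))
  if (is.null(cl_mM) || !is_number(cl_mM) || cl_mM <= 0)
    rf_stop("cl_mM is required: the N/O mixture of the third state depends on it",
            "configuration")
  sl <- scenario$state_lambda_max_nm
  p0_lambda <- scenario_p0_lambda(scenario, cl_mM)
  main0 <- scenario_main_band(scenario, p0_lambda)
  beta <- scenario_beta_band(scenario)
  p0_model <- pigment_spectrum_model(main0, beta)
  v0 <- evaluate_band(main0, wavelengths_nm)

  f_N <- scenario_f_N(scenario, cl_mM)
  state_main <- list(
    evaluate_band(scenario_main_band(scenario, sl$P1), wavelengths_nm),
    evaluate_band(scenario_main_band(scenario, sl$P2), wavelengths_nm),
    f_N * evaluate_band(scenario_main_band(scenario, sl$P3[["N"]]), wavelengths_nm) +
      (1 - f_N) * evaluate_band(scenario_main_band(scenario, sl$P3[["O"]]), wavelengths_nm),
    evaluate_band(scenario_main_band(scenario, sl$P4), wavelengths_nm))
  delta <- do.call(rbind, lapply(state_main, function(v) v - v0))

  p0_spec <- absorption_spectrum(
    wavelengths_nm, evaluate_pigment_model(p0_model, wavelengths_nm),
    label = "P0")
  cycle <- sequential_photocycle(scenario$tau_ms, delta, wavelengths_nm,
                                 p0_spectrum = p0_spec)
  ds <- simulate_dataset(cycle, times_s, noise_sd = noise_sd, seed = seed)
  structure(list(dataset = ds, truth = cycle, p0_model = p0_model,
                 f_N = f_N, cl_mM = cl_mM,
                 state_lambda_max_nm = sl),
            class = "flash_simulation")
}

#' Generate a synthetic series of quasi-equilibrium state spectra
#'
#' One absolute P3 spectrum per Cl- concentration:
#' `f(c) N-band + (1 - f(c)) O-band + beta-band + noise`, with `f` from
#' the release-constant Hill curve.
#'
#' @param scenario An [rmhr_scenario()].
#' @param concentrations_mM Concentrations within (0, 4000] mM, non-empty
#'   (default 8 log-spaced points over 100 mM - 4 M).
#' @param wavelengths_nm Spectral grid.
#' @param noise_sd Spectrum noise SD (OD); default from the scenario.
#' @param seed Seed.
#' @return Object of class `p3_series`: `series` (list of
#'   `list(conc_mM, spectrum)`), `truth` (band objects, per-concentration
#'   f, Kd, n), `beta`.
#' @export
make_p3_series <- function(scenario,
                           concentrations_mM = pmin(4000, 10^seq(log10(100), log10(4000),
                                                                 length.out = 8)),
                           wavelengths_nm = seq(400, 710, 10),
                           noise_sd = scenario$noise$spectrum_od,
                           seed = scenario$seed) {
  stopifnot(inherits(scenario, "rmhr_scenario"))
  if (length(concentrations_mM) == 0)
    rf_stop("concentration list is empty", "domain")
  if (any(concentrations_mM <= 0 | concentrations_mM > 4000))
    rf_stop("concentrations must lie within (0, 4000] mM", "domain")
  band_N <- scenario_main_band(scenario, scenario$state_lambda_max_nm$P3[["N"]])
  band_O <- scenario_main_band(scenario, scenario$state_lambda_max_nm$P3[["O"]])
  beta <- scenario_beta_band(scenario)
  vN <- evaluate_band(band_N, wavelengths_nm)
  vO <- evaluate_band(band_O, wavelengths_nm)
  vB <- evaluate_band(beta, wavelengths_nm)
  f <- scenario_f_N(scenario, concentrations_mM)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  series <- lapply(seq_along(concentrations_mM), function(i) {
    y <- f[i] * vN + (1 - f[i]) * vO + vB +
      stats::rnorm(length(wavelengths_nm), 0, noise_sd)
    list(conc_mM = concentrations_mM[i],
         spectrum = absorption_spectrum(
           wavelengths_nm, y,
           label = sprintf("P3 at %.5g mM Cl-", concentrations_mM[i])))
  })
  structure(list(series = series,
                 truth = list(band_N = band_N, band_O = band_O,
                              f_N = f, Kd = scenario$kd_rel_mM,
                              n = scenario$hill_n, noise_sd = noise_sd,
                              seed = seed),
                 beta = beta),
            class = "p3_series")
}
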