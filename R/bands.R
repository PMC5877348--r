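#' Skewed-Gaussian (Fraser-Suzuki) absorption band
#'
#' Parametric asymmetric absorption band defined in wavenumber
#' (energy) space, where retinal-protein absorption bands are close to
#' symmetric. The band is
#' \deqn{A(\nu) = A_{max} \exp\{-\ln 2 \, [\ln(1 + 2 b (\nu - \nu_{max})/\Delta\nu) / b]^2\}}
#' with position \eqn{\nu_{max}} (cm^-1), full width at half maximum
#' \eqn{\Delta\nu} (cm^-1), peak amplitude \eqn{A_{max}} and dimensionless
#' skew \eqn{b}. Where the logarithm's argument is non-positive the band is
#' exactly zero; the \eqn{b \to 0} limit is the symmetric Gaussian of the
#' same position, width and amplitude. The mode of this form is exactly at
#' `nu_max`, where the band equals `amplitude`.
#'
#' @param nu_max_cm1 Band position in wavenumber (cm^-1).
#' @param amplitude Peak absorbance (OD), non-negative.
#' @param width_cm1 Full width at half maximum (cm^-1), positive.
#' @param skew Dimensionless asymmetry parameter (0 = symmetric Gaussian).
#' @return Object of class `skewed_gaussian_band`.
#' @seealso [band_at_lambda()] to specify the position in nm,
#'   [evaluate_band()], [fit_bands()].
#' @export
skewed_gaussian_band <- function(nu_max_cm1, amplitude, width_cm1, skew = 0) {
  if (!is_number(nu_max_cm1) || nu_max_cm1 <= 0)
    rf_stop("nu_max_cm1 must be a positive number", "invalid")
  if (!is_number(amplitude) || amplitude < 0)
    rf_stop("amplitude must be non-negative", "invalid")
  if (!is_number(width_cm1) || width_cm1 <= 0)
    rf_stop("width_cm1 must be positive", "invalid")
  if (!is_number(skew)) rf_stop("skew must be a number", "invalid")
  structure(
    list(nu_max_cm1 = nu_max_cm1, amplitude = amplitude,
         width_cm1 = width_cm1, skew = skew),
    class = "skewed_gaussian_band"
  )
}

#' @rdname skewed_gaussian_band
#' @param lambda_max_nm Band position as a wavelength in nm
#'   (converted via \eqn{\nu = 10^7/\lambda}).
#' @export
band_at_lambda <- function(lambda_max_nm, amplitude, width_cm1, skew = 0) {
  if (!is_number(lambda_max_nm) || lambda_max_nm <= 0)
    rf_stop("lambda_max_nm must be a positive number", "invalid")
  skewed_gaussian_band(1e7 / lambda_max_nm, amplitude, width_cm1, skew)
}

#' @export
print.skewed_gaussian_band <- function(x, ...) {
  cat(sprintf(
    "<skewed_gaussian_band: %.0f cm-1 (%.1f nm), amp %.4g, fwhm %.0f cm-1, skew %.3g>\n",
    x$nu_max_cm1, 1e7 / x$nu_max_cm1, x$amplitude, x$width_cm1, x$skew))
  invisible(x)
}

#' Evaluate a band on a wavelength grid
#'
#' @param band A [skewed_gaussian_band()].
#' @param wavelengths_nm Positive wavelengths (nm); evaluation is carried
#'   out in wavenumber.
#' @return Non-negative absorbance vector; exactly 0 outside the band's
#'   support.
#' @export
evaluate_band <- function(band, wavelengths_nm) {
  stopifnot(inherits(band, "skewed_gaussian_band"))
  if (any(!is.finite(wavelengths_nm)) || any(wavelengths_nm <= 0))
    rf_stop("wavelengths must be positive and finite", "invalid")
  eval_band_nu(band$nu_max_cm1, band$amplitude, band$width_cm1, band$skew,
               1e7 / wavelengths_nm)
}

# raw evaluator in wavenumber, used by the fitters (no class overhead)
eval_band_nu <- function(nu_max, amplitude, width, skew, nu) {
  dv <- nu - nu_max
  if (abs(skew) < 1e-8) {
    return(amplitude * exp(-log(2) * (2 * dv / width)^2))
  }
  arg <- 1 + 2 * skew * dv / width
  y <- numeric(length(nu))
  ok <- arg > 0
  y[ok] <- amplitude * exp(-log(2) * (log(arg[ok]) / skew)^2)
  y
}

#' Pigment spectrum model: main band + beta-band + scattering baseline
#'
#' Model of the pure retinal absorption spectrum of a rhodopsin pigment:
#' a main visible band, a secondary short-wavelength beta-band of the
#' chromophore, and a Rayleigh-like scattering baseline
#' `baseline_coeff * (lambda/550)^-4` typical of detergent-solubilized
#' samples.
#'
#' @param main_band,beta_band [skewed_gaussian_band()] objects.
#' @param baseline_coeff Non-negative amplitude of the lambda^-4 term at
#'   the 550-nm reference wavelength.
#' @export
pigment_spectrum_model <- function(main_band, beta_band, baseline_coeff = 0) {
  stopifnot(inherits(main_band, "skewed_gaussian_band"),
            inherits(beta_band, "skewed_gaussian_band"))
  if (!is_number(baseline_coeff) || baseline_coeff < 0)
    rf_stop("baseline_coeff must be non-negative", "invalid")
  structure(list(main_band = main_band, beta_band = beta_band,
                 baseline_coeff = baseline_coeff),
            class = "pigment_spectrum_model")
}

#' @rdname pigment_spectrum_model
#' @param model A `pigment_spectrum_model`.
#' @param wavelengths_nm Evaluation grid (nm).
#' @return Absorbance vector (main + beta + baseline), non-negative.
#' @export
evaluate_pigment_model <- function(model, wavelengths_nm) {
  stopifnot(inherits(model, "pigment_spectrum_model"))
  evaluate_band(model$main_band, wavelengths_nm) +
    evaluate_band(model$beta_band, wavelengths_nm) +
    model$baseline_coeff * (wavelengths_nm / 550)^-4
}

#' Decompose a spectrum into skewed-Gaussian bands
#'
#' Least-squares fit of a sum of `n_bands` skewed-Gaussian bands plus an
#' optional lambda^-4 scattering baseline to a measured spectrum, in
#' wavenumber space. Used to extract the pure pigment spectrum (main band
#' plus beta-band) from a measured initial-state spectrum.
#'
#' Fitting uses Levenberg-Marquardt with box constraints
#' (amplitude >= 0, width > 0, |skew| <= 1) and a small number of jittered
#' restarts from the initial guess to escape local minima; the restart with
#' the lowest residual SD wins.
#'
#' @param spectrum An [absorption_spectrum()].
#' @param n_bands Number of bands, >= 1.
#' @param init Optional list of [skewed_gaussian_band()] initial guesses
#'   (length `n_bands`). If omitted, the first band starts at the spectrum
#'   maximum and further bands are staggered to shorter wavelengths.
#' @param baseline Logical; include the scattering baseline term.
#' @param window `c(min_nm, max_nm)` fit window (default 400-710 nm).
#' @param n_restarts Number of jittered restarts (default 5).
#' @param seed Seed for the restart jitter.
#' @return List with `bands` (sorted by `nu_max_cm1` descending, i.e.
#'   shortest wavelength first), `baseline_coeff`, `residual_sd`,
#'   `fitted`, `converged`.
#' @export
fit_bands <- function(spectrum, n_bands, init = NULL, baseline = TRUE,
                      window = c(400, 710), n_restarts = 5, seed = 1) {
  stopifnot(inherits(spectrum, "absorption_spectrum"))
  if (!is_number(n_bands) || n_bands < 1)
    rf_stop("n_bands must be >= 1", "invalid")
  n_bands <- as.integer(n_bands)
  keep <- spectrum$wavelengths_nm >= window[1] &
    spectrum$wavelengths_nm <= window[2]
  if (sum(keep) < 4 * n_bands + baseline)
    rf_stop("spectrum does not cover the fit window densely enough", "invalid")
  wl <- spectrum$wavelengths_nm[keep]
  y <- spectrum$absorbance[keep]
  nu <- 1e7 / wl

  if (is.null(init)) {
    i_max <- which.max(y)
    init <- vector("list", n_bands)
    for (b in seq_len(n_bands)) {
      # stagger extra bands toward higher wavenumber (shorter wavelength)
      init[[b]] <- skewed_gaussian_band(
        nu_max_cm1 = 1e7 / wl[i_max] + (b - 1) * 4000,
        amplitude = max(y[i_max], 1e-6) / b,
        width_cm1 = 3500, skew = 0.1)
    }
  }
  if (length(init) != n_bands)
    rf_stop("init must supply one guess per band", "invalid")

  # parameter vector: per band (nu_max, amplitude, width, skew) [+ baseline]
  pack <- function(bands, base) {
    p <- unlist(lapply(bands, function(b)
      c(b$nu_max_cm1, b$amplitude, b$width_cm1, b$skew)))
    if (baseline) c(p, base) else p
  }
  model_of <- function(p) {
    m <- numeric(length(nu))
    for (b in seq_len(n_bands)) {
      q <- p[(4 * (b - 1) + 1):(4 * b)]
      m <- m + eval_band_nu(q[1], q[2], q[3], q[4], nu)
    }
    if (baseline) m <- m + p[4 * n_bands + 1] * (wl / 550)^-4
    m
  }
  resid_fn <- function(p) y - model_of(p)
  lower <- rep(c(1e7 / 1000, 0, 200, -1), n_bands)
  upper <- rep(c(1e7 / 300, Inf, 20000, 1), n_bands)
  if (baseline) { lower <- c(lower, 0); upper <- c(upper, Inf) }

  p0 <- pack(init, 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    p_start <- p0
    if (r > 1) {
      for (b in seq_len(n_bands)) {
        j <- 4 * (b - 1)
        p_start[j + 1] <- p0[j + 1] + stats::rnorm(1, 0, 300)
        p_start[j + 3] <- p0[j + 3] * stats::runif(1, 0.8, 1.25)
        p_start[j + 4] <- p0[j + 4] + stats::rnorm(1, 0, 0.1)
      }
    }
    p_start <- pmin(pmax(p_start, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(p_start, lower, upper, resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rsd <- sqrt(mean(resid_fn(fit$par)^2))
    if (is.null(best) || rsd < best$rsd)
      best <- list(fit = fit, rsd = rsd)
  }
  if (is.null(best))
    rf_stop("band fit failed to converge", "convergence")
  p <- best$fit$par
  bands <- lapply(seq_len(n_bands), function(b) {
    q <- p[(4 * (b - 1) + 1):(4 * b)]
    skewed_gaussian_band(q[1], max(q[2], 0), q[3], q[4])
  })
  ord <- order(vapply(bands, `[[`, 0, "nu_max_cm1"), decreasing = TRUE)
  conv <- best$fit$info %in% 1:4
  if (!conv)
    rf_stop("band fit did not converge; best-so-far parameters attached",
            "convergence", data = list(bands = bands[ord], residual_sd = best$rsd))
  list(bands = bands[ord],
       baseline_coeff = if (baseline) p[4 * n_bands + 1] else 0,
       residual_sd = best$rsd,
       fitted = model_of(p),
       wavelengths_nm = wl,
       converged = conv)
}
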