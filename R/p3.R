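#' Decompose the quasi-equilibrium P3 spectrum into N-like and O-like bands
#'
#' The third kinetic state of a chloride-pumping photocycle can be a rapid
#' N <-> O quasi-equilibrium whose composition depends on the Cl-
#' concentration. With the main-band shapes of both intermediates and the
#' chromophore beta-band fixed, its absolute spectrum is
#' `f * Abs(N, lambda) + (1 - f) * Abs(O, lambda) + Abs(beta, lambda)`
#' and the N-like fraction f is the single free parameter. f then has a
#' closed-form linear least-squares solution, clipped to `[0, 1]`.
#'
#' @param p3_spectrum [absorption_spectrum()] of the P3 state.
#' @param band_N,band_O [skewed_gaussian_band()] main bands of the N-like
#'   and O-like intermediates (fixed).
#' @param beta [skewed_gaussian_band()] beta-band, taken unchanged from the
#'   unphotolyzed-state decomposition (not refit).
#' @return Object of class `p3_decomposition`: `f_N`, `f_O = 1 - f_N`,
#'   `se_f`, `band_N`, `band_O`, `beta`, `residual_sd`, `clipped`.
#' @export
decompose_p3 <- function(p3_spectrum, band_N, band_O, beta) {
  stopifnot(inherits(p3_spectrum, "absorption_spectrum"),
            inherits(band_N, "skewed_gaussian_band"),
            inherits(band_O, "skewed_gaussian_band"),
            inherits(beta, "skewed_gaussian_band"))
  if (isTRUE(all.equal(unclass(band_N), unclass(band_O))))
    rf_stop("band_N and band_O are identical: fraction is unidentifiable",
            "identifiability")
  wl <- p3_spectrum$wavelengths_nm
  vN <- evaluate_band(band_N, wl)
  vO <- evaluate_band(band_O, wl)
  vB <- evaluate_band(beta, wl)
  y <- p3_spectrum$absorbance - vB
  d <- vN - vO
  ss <- sum(d^2)
  if (ss <= 0)
    rf_stop("bands do not differ on this grid", "identifiability")
  f_raw <- sum((y - vO) * d) / ss
  clipped <- f_raw < 0 || f_raw > 1
  f <- min(max(f_raw, 0), 1)
  res <- y - (f * vN + (1 - f) * vO)
  rsd <- sqrt(mean(res^2))
  structure(list(f_N = f, f_O = 1 - f, f_raw = f_raw,
                 se_f = rsd * sqrt(length(res) / max(1, length(res) - 1)) / sqrt(ss),
                 band_N = band_N, band_O = band_O, beta = beta,
                 residual_sd = rsd, clipped = clipped),
            class = "p3_decomposition")
}

#' @export
print.p3_decomposition <- function(x, ...) {
  cat(sprintf("<p3_decomposition: f_N = %.3f, f_O = %.3f (rsd %.3g OD%s)>\n",
              x$f_N, x$f_O, x$residual_sd,
              if (x$clipped) ", clipped" else ""))
  invisible(x)
}

#' Shared-band decomposition of a concentration series of P3 spectra
#'
#' Simultaneously decomposes P3 spectra measured at several Cl-
#' concentrations, with a single shared pair of N-like/O-like band shapes
#' and one fraction per concentration. The algorithm is block coordinate
#' descent: given the bands, every fraction has the closed-form solution
#' of [decompose_p3()]; given the fractions, the eight band parameters
#' (position, amplitude, width, skew for each band) are refit by
#' Levenberg-Marquardt over the whole stacked series. Iteration stops when
#' no fraction moves by more than `tol` or after `max_rounds` rounds.
#'
#' @param p3_series List of `list(conc_mM = , spectrum = )` entries, or the
#'   object returned by [make_p3_series()]; at least 3 concentrations.
#' @param beta Fixed beta-band ([skewed_gaussian_band()]).
#' @param init_N,init_O Initial band guesses; defaults are bands at 520 and
#'   590 nm with width 3500 cm-1 and skew 0.2, scaled to the data.
#' @param max_rounds,tol Block-descent controls.
#' @return List with `band_N` (shorter-wavelength band), `band_O`,
#'   `fractions` (data frame `conc_mM`, `f_N`, `f_O`, `residual_sd`),
#'   `rounds`, `converged`.
#' @export
fit_shared_bands <- function(p3_series, beta, init_N = NULL, init_O = NULL,
                             max_rounds = 50, tol = 1e-4) {
  if (inherits(p3_series, "p3_series")) p3_series <- p3_series$series
  if (!is.list(p3_series) || length(p3_series) < 3)
    rf_stop("need at least 3 concentrations spanning the transition",
            "identifiability")
  conc <- vapply(p3_series, function(e) as.numeric(e$conc_mM), 0)
  specs <- lapply(p3_series, `[[`, "spectrum")
  wl <- specs[[1]]$wavelengths_nm
  for (s in specs)
    if (!isTRUE(all.equal(s$wavelengths_nm, wl)))
      rf_stop("all spectra in the series must share one grid", "dimension")
  if (length(unique(conc)) < 3)
    rf_stop("concentrations are degenerate", "identifiability")
  Y <- vapply(specs, `[[`, numeric(length(wl)), "absorbance")  # [wl x conc]
  vB <- evaluate_band(beta, wl)
  amp0 <- max(Y - vB)
  if (is.null(init_N)) init_N <- band_at_lambda(520, amp0, 3500, 0.2)
  if (is.null(init_O)) init_O <- band_at_lambda(590, amp0, 3500, 0.2)

  band_par <- c(init_N$nu_max_cm1, init_N$amplitude, init_N$width_cm1, init_N$skew,
                init_O$nu_max_cm1, init_O$amplitude, init_O$width_cm1, init_O$skew)
  lower <- rep(c(1e7 / 800, 0, 500, -1), 2)
  upper <- rep(c(1e7 / 350, Inf, 15000, 1), 2)
  nu <- 1e7 / wl
  bands_of <- function(p) list(
    N = skewed_gaussian_band(p[1], max(p[2], 0), p[3], p[4]),
    O = skewed_gaussian_band(p[5], max(p[6], 0), p[7], p[8]))
  f <- rep(0.5, length(conc))
  rounds <- 0L
  converged <- FALSE
  repeat {
    rounds <- rounds + 1L
    b <- bands_of(band_par)
    f_new <- vapply(seq_along(conc), function(i)
      decompose_p3(specs[[i]], b$N, b$O, beta)$f_N, 0)
    shift <- max(abs(f_new - f))
    f <- f_new
    if (shift < tol && rounds > 1L) { converged <- TRUE; break }
    if (rounds >= max_rounds) break
    resid_fn <- function(p) {
      vN <- eval_band_nu(p[1], p[2], p[3], p[4], nu)
      vO <- eval_band_nu(p[5], p[6], p[7], p[8], nu)
      M <- outer(vN, f) + outer(vO, 1 - f) + vB
      as.numeric(Y - M)
    }
    fit <- minpack.lm::nls.lm(band_par, lower, upper, resid_fn,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    band_par <- fit$par
  }
  b <- bands_of(band_par)
  # order so band_N is the shorter-wavelength (higher-wavenumber) band
  if (b$N$nu_max_cm1 < b$O$nu_max_cm1) {
    b <- list(N = b$O, O = b$N)
    f <- 1 - f
  }
  rsd <- vapply(seq_along(conc), function(i)
    decompose_p3(specs[[i]], b$N, b$O, beta)$residual_sd, 0)
  ord <- order(conc)
  list(band_N = b$N, band_O = b$O,
       fractions = data.frame(conc_mM = conc[ord], f_N = f[ord],
                              f_O = 1 - f[ord], residual_sd = rsd[ord]),
       rounds = rounds, converged = converged)
}
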