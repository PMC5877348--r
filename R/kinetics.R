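#' Irreversible sequential photocycle model
#'
#' Container for a sequential first-order photocycle
#' P0 -> P1 -> ... -> Pn -> P0 with time constants `tau_ms` (strictly
#' increasing) and one difference spectrum per kinetic state
#' (Delta-epsilon_i = spectrum of Pi minus spectrum of P0, in delta-OD, on
#' a common wavelength grid). Each kinetic state may itself be a
#' quasi-equilibrium mixture of physical intermediates; the chain stays
#' n-state and the mixing is carried entirely by that state's difference
#' spectrum.
#'
#' @param tau_ms Time constants in ms, strictly positive and strictly
#'   increasing.
#' @param state_delta_spectra Matrix `[state x wavelength]` of difference
#'   spectra (delta-OD).
#' @param wavelengths_nm Common wavelength grid (nm).
#' @param p0_spectrum Optional [absorption_spectrum()] of the unphotolyzed
#'   state on the same grid.
#' @return Object of class `sequential_photocycle`.
#' @export
sequential_photocycle <- function(tau_ms, state_delta_spectra, wavelengths_nm,
                                  p0_spectrum = NULL) {
  tau_ms <- as.numeric(tau_ms)
  if (any(tau_ms <= 0)) rf_stop("tau values must be positive", "invalid")
  if (any(diff(tau_ms) <= 0))
    rf_stop("tau values must be strictly increasing", "invalid")
  state_delta_spectra <- as.matrix(state_delta_spectra)
  if (nrow(state_delta_spectra) != length(tau_ms))
    rf_stop("need one difference spectrum per tau", "dimension")
  if (ncol(state_delta_spectra) != length(wavelengths_nm))
    rf_stop("difference spectra and wavelength grid disagree", "dimension")
  if (!is.null(p0_spectrum)) {
    stopifnot(inherits(p0_spectrum, "absorption_spectrum"))
    if (!isTRUE(all.equal(p0_spectrum$wavelengths_nm, as.numeric(wavelengths_nm))))
      rf_stop("p0 spectrum is not on the cycle's wavelength grid", "dimension")
  }
  structure(list(tau_ms = tau_ms,
                 state_delta_spectra = state_delta_spectra,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 p0_spectrum = p0_spectrum),
            class = "sequential_photocycle")
}

#' State occupancies of the sequential chain (Bateman closed form)
#'
#' Exact analytic solution of the irreversible linear chain
#' P1 -> P2 -> ... -> Pn -> (ground) with rate constants k_i = 1/tau_i and
#' unit initial population in P1:
#' \deqn{P_j(t) = \prod_{i<j} k_i \; \sum_{i \le j}
#'   \frac{e^{-k_i t}}{\prod_{l \le j, l \ne i}(k_l - k_i)}.}
#' The remainder 1 - sum_j P_j(t) has completed the cycle and returned to
#' the ground state.
#'
#' @param tau_ms Strictly positive, pairwise distinct time constants (ms).
#' @param times_s Non-negative times (s).
#' @return Matrix `[state x time]` of occupancies in `[0, 1]`.
#' @export
state_populations <- function(tau_ms, times_s) {
  if (any(tau_ms <= 0)) rf_stop("tau values must be positive", "invalid")
  if (any(times_s < 0)) rf_stop("times must be non-negative", "invalid")
  C <- bateman_coefficients(tau_ms)
  k <- 1 / (tau_ms * 1e-3)                       # s^-1
  E <- exp(-outer(k, times_s))                   # [state x time]
  P <- C %*% E
  dimnames(P) <- list(paste0("P", seq_along(tau_ms)), NULL)
  P
}

#' Bateman coefficient matrix of the chain
#'
#' `C[j, i]` is the coefficient of `exp(-t/tau_i)` in the occupancy of
#' state j, so that `populations = C %*% exp(-k t)`. The matrix is lower
#' triangular with unit (1,1) entry and encodes the exact algebraic link
#' between kinetic-state difference spectra and the amplitudes of a
#' multi-exponential representation.
#'
#' @inheritParams state_populations
#' @return `n x n` lower-triangular matrix.
#' @export
bateman_coefficients <- function(tau_ms) {
  tau_ms <- as.numeric(tau_ms)
  n <- length(tau_ms)
  if (any(tau_ms <= 0)) rf_stop("tau values must be positive", "invalid")
  if (anyDuplicated(tau_ms))
    rf_stop(paste("duplicate tau values make the chain degenerate;",
                  "perturb them slightly (distinct tau are required)"),
            "degeneracy")
  k <- 1 / (tau_ms * 1e-3)
  C <- matrix(0, n, n)
  for (j in seq_len(n)) {
    pk <- prod(k[seq_len(j - 1)])
    for (i in seq_len(j)) {
      denom <- prod(k[setdiff(seq_len(j), i)] - k[i])
      C[j, i] <- pk / denom
    }
  }
  C
}

#' Exponential amplitudes of the noiseless forward model
#'
#' For a sequential photocycle the noiseless signal at wavelength lambda is
#' `sum_j delta_eps_j(lambda) P_j(t)`, which is exactly a sum of
#' exponentials `sum_i A_i(lambda) exp(-t/tau_i)`. This returns the exact
#' amplitude matrix `A = t(C) %*% delta_eps` (Bateman algebra); the inverse
#' map is [states_from_amplitudes()]. An attribute `ill_conditioned` is set
#' when adjacent time constants are closer than a factor 1.01, where the
#' linear map becomes numerically delicate.
#'
#' @param cycle A [sequential_photocycle()].
#' @return Matrix `[exponential i x wavelength]` of amplitudes A_i(lambda).
#' @export
amplitudes_from_states <- function(cycle) {
  stopifnot(inherits(cycle, "sequential_photocycle"))
  C <- bateman_coefficients(cycle$tau_ms)
  A <- t(C) %*% cycle$state_delta_spectra
  r <- cycle$tau_ms[-1] / cycle$tau_ms[-length(cycle$tau_ms)]
  attr(A, "ill_conditioned") <- length(r) > 0 && any(r < 1.01)
  A
}

#' @rdname amplitudes_from_states
#' @param amplitudes Matrix `[exponential x wavelength]` of amplitudes for
#'   `exp(-t/tau_i)`.
#' @param tau_ms The (distinct) time constants the amplitudes belong to.
#' @return Matrix `[state x wavelength]` of difference spectra.
#' @export
states_from_amplitudes <- function(amplitudes, tau_ms) {
  amplitudes <- as.matrix(amplitudes)
  C <- bateman_coefficients(tau_ms)
  if (nrow(amplitudes) != length(tau_ms))
    rf_stop("one amplitude row per tau required", "dimension")
  solve(t(C), amplitudes)
}

#' Logarithmic flash-photolysis time grid
#'
#' @param t_min_s,t_max_s Time span in seconds (defaults 10 us to 388 ms).
#' @param points_per_decade Grid density (default 30).
#' @return Strictly increasing times in seconds.
#' @export
flash_time_grid <- function(t_min_s = 1e-5, t_max_s = 0.388,
                            points_per_decade = 30) {
  if (t_min_s <= 0 || t_max_s <= t_min_s)
    rf_stop("need 0 < t_min_s < t_max_s", "invalid")
  n <- max(2L, ceiling(log10(t_max_s / t_min_s) * points_per_decade) + 1L)
  10^seq(log10(t_min_s), log10(t_max_s), length.out = n)
}

#' Flash-photolysis dataset container
#'
#' Wavelength-by-time matrix of flash-induced absorbance differences
#' (delta-OD) plus acquisition metadata.
#'
#' @param wavelengths_nm Wavelength grid (nm), strictly increasing.
#' @param times_s Times (s), strictly increasing, all at or above
#'   `artifact_cutoff_s`.
#' @param delta_abs Matrix `[wavelength x time]` of delta-OD values.
#' @param n_averaged Number of averaged flashes (metadata).
#' @param artifact_cutoff_s Earliest trusted time; data before it are
#'   contaminated by the laser scattering artifact.
#' @export
flash_photolysis_dataset <- function(wavelengths_nm, times_s, delta_abs,
                                     n_averaged = 30,
                                     artifact_cutoff_s = 1e-5) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  times_s <- as.numeric(times_s)
  delta_abs <- as.matrix(delta_abs)
  if (any(diff(wavelengths_nm) <= 0))
    rf_stop("wavelengths must be strictly increasing", "format")
  if (any(diff(times_s) <= 0))
    rf_stop("times must be strictly increasing", "format")
  if (any(times_s < artifact_cutoff_s))
    rf_stop("times below the artifact cutoff must be trimmed before construction",
            "invalid")
  if (nrow(delta_abs) != length(wavelengths_nm) ||
      ncol(delta_abs) != length(times_s))
    rf_stop("delta_abs dimensions do not match the grids", "dimension")
  structure(list(wavelengths_nm = wavelengths_nm, times_s = times_s,
                 delta_abs = delta_abs, n_averaged = n_averaged,
                 artifact_cutoff_s = artifact_cutoff_s),
            class = "flash_photolysis_dataset")
}

#' @export
print.flash_photolysis_dataset <- function(x, ...) {
  cat(sprintf(
    "<flash_photolysis_dataset: %d wavelengths (%.0f-%.0f nm), %d times (%.3g-%.3g s), %d flashes averaged>\n",
    length(x$wavelengths_nm), min(x$wavelengths_nm), max(x$wavelengths_nm),
    length(x$times_s), min(x$times_s), max(x$times_s), x$n_averaged))
  invisible(x)
}

#' Simulate a flash-photolysis measurement from a photocycle
#'
#' Forward model: `delta_abs(lambda, t) = sum_i P_i(t) delta_eps_i(lambda)`
#' plus i.i.d. Gaussian noise, reproducible for a given seed.
#'
#' @param cycle A [sequential_photocycle()].
#' @param times_s Measurement times (s), all at or above `artifact_cutoff_s`.
#' @param noise_sd Gaussian noise SD in delta-OD (>= 0).
#' @param seed Integer seed.
#' @param n_averaged,artifact_cutoff_s Metadata passed through.
#' @return A [flash_photolysis_dataset()].
#' @export
simulate_dataset <- function(cycle, times_s = flash_time_grid(),
                             noise_sd = 0, seed = 1, n_averaged = 30,
                             artifact_cutoff_s = 1e-5) {
  stopifnot(inherits(cycle, "sequential_photocycle"))
  if (!is_number(noise_sd) || noise_sd < 0)
    rf_stop("noise_sd must be non-negative", "invalid")
  P <- state_populations(cycle$tau_ms, times_s)
  D <- t(cycle$state_delta_spectra) %*% P     # [wavelength x time]
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    D <- D + matrix(stats::rnorm(length(D), 0, noise_sd), nrow(D), ncol(D))
  }
  flash_photolysis_dataset(cycle$wavelengths_nm, times_s, D,
                           n_averaged = n_averaged,
                           artifact_cutoff_s = artifact_cutoff_s)
}
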