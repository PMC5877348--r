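#' Global multi-exponential fit of a flash-photolysis dataset
#'
#' Fits `delta_abs(lambda, t) = sum_i A_i(lambda) exp(-t/tau_i)` with the
#' time constants shared across all wavelengths, by separable (variable
#' projection) least squares: for any trial tau the per-wavelength
#' amplitudes are the exact linear least-squares solution, and only the
#' tau are optimized nonlinearly, in log10 space with box constraints
#' `[artifact_cutoff/3, 10 * t_max]`. Standard errors of the tau come from
#' the Gauss-Newton curvature of the projected residual at the optimum.
#'
#' @param dataset A prepared (artifact-trimmed, baseline-subtracted)
#'   [flash_photolysis_dataset()].
#' @param n_exponents Number of exponential components, >= 1.
#' @param init_tau_ms Optional initial time constants (ms); default is
#'   log-equally spaced across the observed time decades.
#' @param weights Optional non-negative weight matrix
#'   `[wavelength x time]`; default equal weighting.
#' @return Object of class `global_fit_result` with `tau_ms` (sorted
#'   increasing), `tau_se_ms`, `amplitudes` (`[exponent x wavelength]`),
#'   `residual_sd` (root-mean-square residual, delta-OD), `n_exponents`,
#'   `converged`, `identifiability_warning`, `non_identifiable`.
#' @export
fit_global <- function(dataset, n_exponents, init_tau_ms = NULL,
                       weights = NULL) {
  stopifnot(inherits(dataset, "flash_photolysis_dataset"))
  if (!is_number(n_exponents) || n_exponents < 1)
    rf_stop("n_exponents must be >= 1", "invalid")
  n <- as.integer(n_exponents)
  tt <- dataset$times_s
  D <- dataset$delta_abs
  decades <- log10(max(tt) / min(tt))
  if (decades < n / 2)
    rf_stop("time span too short for the requested number of exponents",
            "invalid")
  ident_warn <- n > decades + 1
  W <- if (is.null(weights)) NULL else sqrt(as.matrix(weights))

  lo_ms <- dataset$artifact_cutoff_s / 3 * 1e3
  hi_ms <- 10 * max(tt) * 1e3
  if (is.null(init_tau_ms)) {
    lt0 <- seq(log10(min(tt) * 1e3), log10(max(tt) * 1e3),
               length.out = n + 2)[seq_len(n) + 1]
  } else {
    if (length(init_tau_ms) != n)
      rf_stop("init_tau_ms must have length n_exponents", "invalid")
    lt0 <- log10(sort(as.numeric(init_tau_ms)))
  }
  lt0 <- pmin(pmax(lt0, log10(lo_ms)), log10(hi_ms))

  # degenerate all-zero input: amplitudes zero, tau stay at initialization
  if (max(abs(D)) < 1e-14) {
    A <- matrix(0, n, length(dataset$wavelengths_nm))
    return(structure(list(
      tau_ms = sort(10^lt0), tau_se_ms = rep(NA_real_, n), amplitudes = A,
      residual_sd = 0, n_exponents = n, converged = TRUE,
      identifiability_warning = ident_warn, non_identifiable = TRUE,
      wavelengths_nm = dataset$wavelengths_nm, times_s = tt,
      n_obs = length(D)), class = "global_fit_result"))
  }

  solve_amplitudes <- function(tau_s) {
    X <- exp(-outer(tt, 1 / tau_s))            # [time x exponent]
    A <- qr.coef(qr(X), t(D))                  # [exponent x wavelength]
    A[is.na(A)] <- 0
    list(X = X, A = A)
  }
  resid_fn <- function(lt) {
    s <- solve_amplitudes(10^lt * 1e-3)
    R <- D - t(s$X %*% s$A)
    if (!is.null(W)) R <- R * W
    as.numeric(R)
  }
  fit <- minpack.lm::nls.lm(
    par = lt0, lower = rep(log10(lo_ms), n), upper = rep(log10(hi_ms), n),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 400, ptol = 1e-12,
                                         ftol = 1e-12))
  converged <- fit$info %in% 1:4
  if (!converged)
    rf_stop(sprintf("global fit did not converge (nls.lm info %d): %s",
                    fit$info, fit$message),
            "convergence",
            data = list(tau_ms = sort(10^fit$par)))
  lt <- fit$par
  ord <- order(lt)
  lt <- lt[ord]
  tau_ms <- 10^lt
  s <- solve_amplitudes(tau_ms * 1e-3)
  res <- resid_fn(lt)
  rsd <- sqrt(mean(res^2))

  # SEs on log10(tau) from finite-difference Gauss-Newton curvature of the
  # projected residual, then delta method back to ms
  tau_se <- rep(NA_real_, n)
  J <- matrix(0, length(res), n)
  h <- 1e-5
  for (i in seq_len(n)) {
    lp <- lt; lp[i] <- lp[i] + h
    lm_ <- lt; lm_[i] <- lm_[i] - h
    J[, i] <- (resid_fn(lp) - resid_fn(lm_)) / (2 * h)
  }
  dof <- max(1, length(res) - n * (1 + nrow(D)))
  sigma2 <- sum(res^2) / dof
  cv <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
  if (!is.null(cv)) tau_se <- tau_ms * log(10) * sqrt(pmax(diag(cv), 0))

  structure(list(
    tau_ms = tau_ms, tau_se_ms = tau_se, amplitudes = s$A[ord, , drop = FALSE],
    residual_sd = rsd, n_exponents = n, converged = TRUE,
    identifiability_warning = ident_warn, non_identifiable = FALSE,
    wavelengths_nm = dataset$wavelengths_nm, times_s = tt,
    n_obs = length(D)), class = "global_fit_result")
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat(sprintf("<global_fit_result: %d exponents, residual SD %.3g dOD%s>\n",
              x$n_exponents, x$residual_sd,
              if (x$non_identifiable) ", NON-IDENTIFIABLE" else ""))
  tab <- data.frame(tau_ms = signif(x$tau_ms, 4),
                    se_ms = signif(x$tau_se_ms, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Select the number of exponential components
#'
#' Fits `n = 1 .. max_n` exponents and chooses the smallest n for which
#' adding one more component reduces the residual standard deviation by
#' less than `threshold` (relative). Each fit beyond n = 1 is warm-started
#' from the previous solution with one extra component inserted in the
#' widest log-time gap, which guarantees the residual SD is non-increasing
#' in n; a cold (log-spaced) start is also tried and the better one kept.
#'
#' @inheritParams fit_global
#' @param max_n Largest component count to try.
#' @param threshold Relative residual-SD reduction below which the extra
#'   component is judged unsupported (default 0.05).
#' @return List with `n_selected`, `table` (data frame `n`, `residual_sd`,
#'   `reduction`, `converged`) and `fits` (the per-n `global_fit_result`s).
#' @export
select_n_exponents <- function(dataset, max_n = 6, threshold = 0.05) {
  stopifnot(inherits(dataset, "flash_photolysis_dataset"))
  if (!is_number(max_n) || max_n < 1) rf_stop("max_n must be >= 1", "invalid")
  max_n <- as.integer(max_n)
  fits <- vector("list", max_n)
  sds <- rep(NA_real_, max_n)
  ok <- logical(max_n)
  for (n in seq_len(max_n)) {
    cand <- list()
    cand$cold <- tryCatch(fit_global(dataset, n), error = function(e) NULL)
    if (n > 1 && ok[n - 1]) {
      prev <- fits[[n - 1]]$tau_ms
      lg <- log10(c(dataset$artifact_cutoff_s * 1e3 / 2, prev,
                    max(dataset$times_s) * 1e3))
      gap <- which.max(diff(lg))
      extra <- 10^((lg[gap] + lg[gap + 1]) / 2)
      cand$warm <- tryCatch(
        fit_global(dataset, n, init_tau_ms = sort(c(prev, extra))),
        error = function(e) NULL)
    }
    cand <- Filter(Negate(is.null), cand)
    if (length(cand) == 0) { ok[n] <- FALSE; next }
    rs <- vapply(cand, `[[`, 0, "residual_sd")
    fits[[n]] <- cand[[which.min(rs)]]
    sds[n] <- min(rs)
    ok[n] <- TRUE
  }
  if (!any(ok)) rf_stop("no exponent count converged", "convergence")
  if (!all(ok))
    rf_warn("some exponent counts failed to converge and were skipped",
            "selection")
  reduction <- rep(NA_real_, max_n)
  for (n in seq_len(max_n - 1)) {
    if (ok[n] && ok[n + 1] && sds[n] > 0)
      reduction[n] <- (sds[n] - sds[n + 1]) / sds[n]
  }
  n_selected <- max(which(ok))
  scale <- max(abs(dataset$delta_abs), .Machine$double.eps)
  for (n in seq_len(max_n)) {
    if (!ok[n]) next
    if (sds[n] <= 1e-10 * scale) { n_selected <- n; break }  # at machine noise
    if (!is.na(reduction[n]) && reduction[n] < threshold) { n_selected <- n; break }
  }
  list(n_selected = n_selected,
       table = data.frame(n = seq_len(max_n), residual_sd = sds,
                          reduction = reduction, converged = ok),
       fits = fits)
}

#' Reconstruct absolute intermediate-state spectra
#'
#' Converts the fitted exponential amplitudes back to kinetic-state
#' difference spectra through the exact sequential-chain algebra
#' ([states_from_amplitudes()]) and adds the unphotolyzed-state spectrum
#' to each, giving the absolute spectra of the states P1..Pn. Each state
#' spectrum is reported with its refined absorption maximum.
#'
#' @param fit A converged [fit_global()] result.
#' @param p0 [absorption_spectrum()] of the unphotolyzed state on the same
#'   wavelength grid as the fit.
#' @return Object of class `state_spectra_set`: `p0`, `states` (list of
#'   [absorption_spectrum()]), `delta` (`[state x wavelength]`),
#'   `lambda_max_nm` (named vector of refined state maxima).
#' @export
reconstruct_states <- function(fit, p0) {
  stopifnot(inherits(fit, "global_fit_result"),
            inherits(p0, "absorption_spectrum"))
  if (!fit$converged) rf_stop("fit has not converged", "invalid")
  if (!isTRUE(all.equal(p0$wavelengths_nm, fit$wavelengths_nm)))
    rf_stop("p0 spectrum is not on the fit's wavelength grid", "dimension")
  delta <- states_from_amplitudes(fit$amplitudes, fit$tau_ms)
  states <- lapply(seq_len(nrow(delta)), function(i)
    absorption_spectrum(p0$wavelengths_nm, p0$absorbance + delta[i, ],
                        label = paste0("P", i)))
  lm <- vapply(states, lambda_max, 0)
  names(lm) <- paste0("P", seq_along(states))
  rownames(delta) <- names(lm)
  structure(list(p0 = p0, states = states, delta = delta,
                 lambda_max_nm = lm),
            class = "state_spectra_set")
}

#' @export
print.state_spectra_set <- function(x, ...) {
  cat(sprintf("<state_spectra_set: P0 + %d states; lambda_max(P0) = %.1f nm>\n",
              length(x$states), lambda_max(x$p0)))
  print(round(x$lambda_max_nm, 1))
  invisible(x)
}
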