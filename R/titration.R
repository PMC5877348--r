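#' Titration curve container
#'
#' Holds one titration experiment: ligand concentration (mM) or pH against
#' an observed quantity (absorption maximum in nm, an intermediate
#' fraction, or a normalized 380-nm absorbance change).
#'
#' @param x Ligand concentration in mM (strictly positive, for
#'   concentration kinds) or pH; sorted increasing.
#' @param y Observed quantity.
#' @param kind One of `"lambda_max"`, `"fraction_N"`, `"fraction_O"`,
#'   `"deltaA_380"`.
#' @return Object of class `titration_curve`.
#' @export
titration_curve <- function(x, y,
                            kind = c("lambda_max", "fraction_N",
                                     "fraction_O", "deltaA_380")) {
  kind <- match.arg(kind)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) rf_stop("x and y lengths differ", "invalid")
  if (length(x) < 4) rf_stop("need at least 4 points to fit", "invalid")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (any(diff(x) <= 0)) rf_stop("x values must be distinct", "invalid")
  if (kind != "deltaA_380" && any(x <= 0))
    rf_stop("concentrations must be strictly positive", "invalid")
  structure(list(x = x, y = y, kind = kind), class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve [%s]: %d points, x in [%.3g, %.3g]>\n",
              x$kind, length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

#' Hill saturation model
#'
#' `y = a + b * x^n / (x^n + Kd^n)`: offset `a`, amplitude `b` (negative
#' for a blue-shifting absorption maximum), dissociation constant `Kd`
#' (mM) and Hill coefficient `n`. `y(0) = a`, `y(Inf) = a + b`, and
#' `y(Kd) = a + b/2` for any n.
#'
#' @param a,b,Kd,n Model parameters; `Kd > 0`.
#' @param x Ligand concentration(s), >= 0.
#' @export
hill_eval <- function(a, b, Kd, n, x) {
  if (!is_number(Kd) || Kd <= 0) rf_stop("Kd must be positive", "invalid")
  if (any(x < 0)) rf_stop("concentrations must be non-negative", "domain")
  # x^n/(x^n + Kd^n) computed stably in log space
  s <- ifelse(x == 0, 0, 1 / (1 + exp(n * (log(Kd) - log(pmax(x, .Machine$double.xmin))))))
  a + b * s
}

new_hill_fit <- function(par, se, rsd, n_obs, extra = list()) {
  structure(c(list(a = par[["a"]], b = par[["b"]], Kd = par[["Kd"]],
                   n = par[["n"]],
                   se_a = se[["a"]], se_b = se[["b"]], se_Kd = se[["Kd"]],
                   se_n = se[["n"]],
                   residual_sd = rsd, n_obs = n_obs), extra),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit: Kd = %.4g +/- %.2g mM, n = %.3g +/- %.2g, a = %.4g, b = %.4g (rsd %.3g)>\n",
              x$Kd, x$se_Kd, x$n, x$se_n, x$a, x$b, x$residual_sd))
  if (!is.null(x$fold_ratio))
    cat(sprintf("  release/uptake Kd fold-ratio: %.3g\n", x$fold_ratio))
  invisible(x)
}

# No-transition guard: F-test of the 4-parameter Hill model against the
# constant model. A flat curve lets the optimizer absorb noise into a sharp
# pseudo-step, so the fitted amplitude alone is not a reliable flag; the
# lack-of-fit improvement over a constant is.
check_transition <- function(y_obs, ss_fit, n_extra_par) {
  m <- length(y_obs)
  ss0 <- sum((y_obs - mean(y_obs))^2)
  dof <- m - n_extra_par - 1
  if (dof < 1) return(invisible(TRUE))
  if (ss0 <= .Machine$double.eps * max(1, mean(y_obs)^2) ||
      ss0 <= ss_fit * (1 + 1e-12)) {
    rf_stop("no transition: data are flat", "no_transition")
  }
  Fstat <- ((ss0 - ss_fit) / n_extra_par) / max(ss_fit / dof, 1e-300)
  p <- stats::pf(Fstat, n_extra_par, dof, lower.tail = FALSE)
  if (p > 0.01)
    rf_stop("no transition: fitted amplitude indistinguishable from noise",
            "no_transition")
  invisible(TRUE)
}

# shared Levenberg-Marquardt core for Hill-type fits.
# par = (a, b, log10 Kd, n); returns fit + covariance-derived SEs.
hill_lm <- function(resid_fn, p0, x_range) {
  lower <- c(-Inf, -Inf, log10(x_range[1] / 100), 0.3)
  upper <- c(Inf, Inf, log10(x_range[2] * 100), 5)
  fit <- minpack.lm::nls.lm(p0, lower, upper, resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ptol = 1e-14, ftol = 1e-14))
  if (!fit$info %in% 1:4)
    rf_stop(sprintf("Hill fit did not converge (info %d)", fit$info),
            "convergence", data = list(par = fit$par))
  res <- resid_fn(fit$par)
  dof <- max(1, length(res) - length(p0))
  sigma2 <- sum(res^2) / dof
  cv <- tryCatch(sigma2 * solve(fit$hessian), error = function(e)
    matrix(NA_real_, length(p0), length(p0)))
  se <- sqrt(pmax(diag(cv), 0))
  list(par = fit$par, se = se, rsd = sqrt(mean(res^2)), n_obs = length(res))
}

#' Fit the Hill equation to a titration curve
#'
#' Nonlinear least squares over `(a, b, log10 Kd, n)`; fitting the
#' dissociation constant in log space keeps it positive and makes the
#' optimization scale-free. The Hill coefficient is bounded to
#' `[0.3, 5]`. Standard errors come from the curvature at the optimum
#' (`se_Kd` by the delta method from `log10 Kd`).
#'
#' @param curve A [titration_curve()] with >= 4 points.
#' @param init Optional named list overriding initial values
#'   (`a`, `b`, `Kd`, `n`).
#' @return A `hill_fit` object: `a`, `b`, `Kd` (mM), `n`, standard errors,
#'   `residual_sd`.
#' @export
fit_hill <- function(curve, init = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  x <- curve$x; y <- curve$y
  p0 <- c(a = y[1], b = y[length(y)] - y[1],
          lKd = log10(exp(mean(log(range(x))))), n = 1)
  if (!is.null(init)) {
    if (!is.null(init$a)) p0[1] <- init$a
    if (!is.null(init$b)) p0[2] <- init$b
    if (!is.null(init$Kd)) p0[3] <- log10(init$Kd)
    if (!is.null(init$n)) p0[4] <- init$n
  }
  resid_fn <- function(p) y - hill_eval(p[1], p[2], 10^p[3], p[4], x)
  out <- hill_lm(resid_fn, p0, range(x))
  out$par <- unname(out$par); out$se <- unname(out$se)
  Kd <- 10^out$par[3]
  check_transition(y, sum(resid_fn(out$par)^2), 3)
  new_hill_fit(
    par = c(a = out$par[[1]], b = out$par[[2]], Kd = Kd, n = out$par[[4]]),
    se = c(a = out$se[1], b = out$se[2], Kd = log(10) * Kd * out$se[3],
           n = out$se[4]),
    rsd = out$rsd, n_obs = out$n_obs)
}

#' Fit the Henderson-Hasselbalch equation to a pH titration
#'
#' Single-site model for the alkaline deprotonation of the retinal Schiff
#' base, observed as the rise of the 380-nm band:
#' `deltaA = s / (1 + 10^(pKa - pH))` with optional amplitude scale `s`
#' (fitted, so raw un-normalized data are accepted; `s = 1` for data
#' already normalized to full deprotonation). The fitted curve crosses
#' `s/2` exactly at `pH = pKa`.
#'
#' @param curve A [titration_curve()] of kind `"deltaA_380"`, y increasing
#'   with pH.
#' @param fit_scale Logical; fit the amplitude scale (default TRUE).
#' @return Object of class `pka_fit`: `pKa`, `se_pKa`, `amplitude_scale`,
#'   `residual_sd`. Warns (class `rhodofit_poorly_constrained`) when the
#'   pH range does not bracket the transition and
#'   (class `rhodofit_sanity`) when pKa falls outside 4-14.
#' @export
fit_pka <- function(curve, fit_scale = TRUE) {
  stopifnot(inherits(curve, "titration_curve"))
  if (curve$kind != "deltaA_380")
    rf_stop("fit_pka expects a deltaA_380 curve", "invalid")
  x <- curve$x; y <- curve$y
  if (stats::cor(x, y) < 0)
    rf_stop(paste("deltaA decreases with pH; the 380-nm deprotonation band",
                  "must rise with pH - check the sign convention"),
            "sign_convention")
  s0 <- max(y)
  if (s0 <= 0) rf_stop("deltaA values must reach above 0", "invalid")
  yn <- y / s0
  if (max(yn) < 0.3 || min(yn) > 0.7)
    rf_warn("pH range does not bracket the transition; pKa poorly constrained",
            "poorly_constrained")
  pka0 <- x[which.min(abs(yn - 0.5))]
  resid_fn <- function(p) y - p[2] / (1 + 10^(p[1] - x))
  p0 <- c(pka0, s0)
  if (!fit_scale) resid_fn <- function(p) y - 1 / (1 + 10^(p[1] - x))
  fit <- minpack.lm::nls.lm(if (fit_scale) p0 else p0[1],
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ptol = 1e-14, ftol = 1e-14))
  if (!fit$info %in% 1:4)
    rf_stop("pKa fit did not converge", "convergence")
  res <- resid_fn(fit$par)
  dof <- max(1, length(res) - length(fit$par))
  cv <- tryCatch(sum(res^2) / dof * solve(fit$hessian), error = function(e)
    matrix(NA_real_, length(fit$par), length(fit$par)))
  pka <- fit$par[1]
  if (pka < 4 || pka > 14)
    rf_warn(sprintf("fitted pKa %.2f outside the 4-14 sanity window", pka),
            "sanity")
  structure(list(pKa = pka, se_pKa = sqrt(max(cv[1, 1], 0)),
                 amplitude_scale = if (fit_scale) fit$par[2] else 1,
                 residual_sd = sqrt(mean(res^2)), n_obs = length(res)),
            class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("<pka_fit: pKa = %.3f +/- %.3f (scale %.3g, rsd %.3g)>\n",
              x$pKa, x$se_pKa, x$amplitude_scale, x$residual_sd))
  invisible(x)
}

#' Chloride-release dissociation constant from N/O fraction curves
#'
#' Joint Hill fit of the N-like and O-like fractions of the
#' quasi-equilibrium state against Cl- concentration, with shared offset,
#' amplitude, Kd and Hill coefficient:
#' `f_N = a + b * h(c)` and `f_O = (1 - a) - b * h(c)` where
#' `h(c) = c^n / (c^n + Kd^n)`. The shared Kd is the release constant
#' K_d,rel; when the uptake (initial-state) constant K_d,int is supplied
#' the fold-ratio `K_d,rel / K_d,int` is reported.
#'
#' @param fraction_table Data frame with columns `conc_mM`, `f_N`, `f_O`
#'   (as returned by [fit_shared_bands()]), >= 4 concentrations.
#' @param kd_int_mM Optional initial-state dissociation constant (mM) for
#'   the fold-ratio.
#' @return A `hill_fit` describing the f_N branch, with extra fields
#'   `kd_rel_mM`, `kd_int_mM`, `fold_ratio`.
#' @export
release_constant <- function(fraction_table, kd_int_mM = NULL) {
  ft <- as.data.frame(fraction_table)
  need <- c("conc_mM", "f_N", "f_O")
  if (!all(need %in% names(ft)))
    rf_stop("fraction table must have columns conc_mM, f_N, f_O", "invalid")
  if (nrow(ft) < 4) rf_stop("need >= 4 concentrations", "invalid")
  if (any(ft$f_N < -1e-9 | ft$f_N > 1 + 1e-9 |
          ft$f_O < -1e-9 | ft$f_O > 1 + 1e-9))
    rf_stop("fractions must lie in [0, 1]", "invalid")
  if (any(abs(ft$f_N + ft$f_O - 1) > 1e-6))
    rf_stop("f_N and f_O must sum to 1 (complementarity violated)", "invalid")
  x <- ft$conc_mM
  resid_fn <- function(p) {
    h <- hill_eval(0, 1, 10^p[3], p[4], x)
    c(ft$f_N - (p[1] + p[2] * h),
      ft$f_O - ((1 - p[1]) - p[2] * h))
  }
  p0 <- c(a = max(min(ft$f_N), 0), b = diff(range(ft$f_N)),
          lKd = log10(exp(mean(log(range(x))))), n = 1)
  out <- hill_lm(resid_fn, p0, range(x))
  out$par <- unname(out$par); out$se <- unname(out$se)
  # no-transition guard on the stacked two-branch problem: constant model
  # (f_N = a, f_O = 1 - a, one parameter) vs the 4-parameter joint Hill fit
  ss1 <- sum(resid_fn(out$par)^2)
  ss0 <- 2 * sum((ft$f_N - mean(ft$f_N))^2)
  dof <- 2 * nrow(ft) - 4
  flat <- ss0 <= ss1 * (1 + 1e-12) || ss0 <= .Machine$double.eps
  if (!flat && dof >= 1 && ss1 > 0) {
    Fstat <- ((ss0 - ss1) / 3) / (ss1 / dof)
    flat <- stats::pf(Fstat, 3, dof, lower.tail = FALSE) > 0.01
  }
  if (flat)
    rf_stop("fractions do not change with concentration: zero amplitude",
            "no_transition")
  Kd <- 10^out$par[3]
  new_hill_fit(
    par = c(a = out$par[[1]], b = out$par[[2]], Kd = Kd, n = out$par[[4]]),
    se = c(a = out$se[1], b = out$se[2], Kd = log(10) * Kd * out$se[3],
           n = out$se[4]),
    rsd = out$rsd, n_obs = out$n_obs,
    extra = list(kd_rel_mM = Kd, kd_int_mM = kd_int_mM,
                 fold_ratio = if (is.null(kd_int_mM)) NULL else Kd / kd_int_mM))
}
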