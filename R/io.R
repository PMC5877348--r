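# CSV dialect: RFC-4180, UTF-8, '.' decimal, '#' comment lines, floats
# written with 17 significant digits so doubles round-trip exactly.

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Read and write spectrum CSV files
#'
#' Two columns `wavelength_nm,absorbance`; lines starting with `#` are
#' comments (the writer stores the label there).
#'
#' @param spectrum An [absorption_spectrum()].
#' @param path File path.
#' @return `read_spectrum_csv` returns an [absorption_spectrum()];
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "absorption_spectrum"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nzchar(spectrum$label))
    writeLines(paste0("# label: ", spectrum$label), con)
  writeLines("wavelength_nm,absorbance", con)
  writeLines(paste(fmt17(spectrum$wavelengths_nm),
                   fmt17(spectrum$absorbance), sep = ","), con)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  label <- ""
  lab <- grep("^# label:", lines, value = TRUE)
  if (length(lab)) label <- trimws(sub("^# label:", "", lab[1]))
  d <- utils::read.csv(text = lines, comment.char = "#")
  if (!all(c("wavelength_nm", "absorbance") %in% names(d)))
    rf_stop("spectrum CSV must have columns wavelength_nm,absorbance",
            "format")
  absorption_spectrum(d$wavelength_nm, d$absorbance, label = label)
}

#' Write a flash-photolysis dataset as CSV (+ metadata sidecar)
#'
#' First column `time_s`, remaining columns `wl_<nm>`, values in
#' delta-OD. A JSON sidecar `<path>.json` holds `n_averaged`,
#' `artifact_cutoff_s` and `temperature_C`.
#'
#' @param dataset A [flash_photolysis_dataset()].
#' @param path CSV path.
#' @param temperature_C Metadata (default 20).
#' @param sidecar Write the JSON sidecar (default TRUE).
#' @export
write_flash_csv <- function(dataset, path, temperature_C = 20,
                            sidecar = TRUE) {
  stopifnot(inherits(dataset, "flash_photolysis_dataset"))
  header <- paste(c("time_s", paste0("wl_", dataset$wavelengths_nm)),
                  collapse = ",")
  rows <- vapply(seq_along(dataset$times_s), function(j)
    paste(c(fmt17(dataset$times_s[j]), fmt17(dataset$delta_abs[, j])),
          collapse = ","), "")
  writeLines(c(header, rows), path, useBytes = TRUE)
  if (sidecar) {
    jsonlite::write_json(
      list(n_averaged = dataset$n_averaged,
           artifact_cutoff_s = dataset$artifact_cutoff_s,
           temperature_C = temperature_C),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Load and prepare a flash-photolysis CSV
#'
#' Reads the `time_s` / `wl_<nm>` dialect and applies the measurement
#' preparation steps: rows recorded before the laser pulse (t <= 0) define
#' the per-wavelength baseline, which is subtracted and dropped; rows
#' earlier than `artifact_cutoff_s` (laser scattering artifact window) are
#' discarded.
#'
#' @param path CSV path (a `<path>.json` sidecar is honored if present).
#' @param artifact_cutoff_s Earliest trusted time (default 10 us, or the
#'   sidecar value).
#' @return A [flash_photolysis_dataset()].
#' @export
load_flash_dataset <- function(path, artifact_cutoff_s = NULL) {
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(d))
    rf_stop("flash CSV must have a time_s column", "format")
  wl_cols <- grep("^wl_", names(d), value = TRUE)
  if (length(wl_cols) == 0)
    rf_stop("flash CSV has no wavelength columns (wl_<nm>)", "format")
  wl <- as.numeric(sub("^wl_", "", wl_cols))
  if (any(is.na(wl)))
    rf_stop(paste("malformed wavelength column name:",
                  wl_cols[which(is.na(wl))[1]]), "format")
  ord <- order(wl)
  wl <- wl[ord]; wl_cols <- wl_cols[ord]
  tt <- d$time_s
  if (any(diff(tt) <= 0))
    rf_stop("time column must be strictly increasing", "format")
  meta <- list(n_averaged = 30, artifact_cutoff_s = 1e-5)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    m <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(m)] <- m
  }
  if (is.null(artifact_cutoff_s)) artifact_cutoff_s <- meta$artifact_cutoff_s
  D <- t(as.matrix(d[, wl_cols, drop = FALSE]))   # [wavelength x time]
  pre <- tt <= 0
  if (any(pre)) {
    baseline <- rowMeans(D[, pre, drop = FALSE])
    D <- D - baseline
    D <- D[, !pre, drop = FALSE]
    tt <- tt[!pre]
  }
  keep <- tt >= artifact_cutoff_s
  if (!any(keep))
    rf_stop("no data at or after the artifact cutoff", "format")
  flash_photolysis_dataset(wl, tt[keep], D[, keep, drop = FALSE],
                           n_averaged = meta$n_averaged,
                           artifact_cutoff_s = artifact_cutoff_s)
}

#' Read and write titration CSV files
#'
#' Two columns whose header names the observable:
#' `conc_mM,lambda_max_nm`, `conc_mM,f_N`, `conc_mM,f_O` or
#' `pH,deltaA_380`; the reader infers the curve kind from the header.
#'
#' @param curve A [titration_curve()].
#' @param path File path.
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  header <- switch(curve$kind,
    lambda_max = "conc_mM,lambda_max_nm",
    fraction_N = "conc_mM,f_N",
    fraction_O = "conc_mM,f_O",
    deltaA_380 = "pH,deltaA_380")
  writeLines(c(header, paste(fmt17(curve$x), fmt17(curve$y), sep = ",")),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (ncol(d) < 2) rf_stop("titration CSV needs two columns", "format")
  kind <- switch(names(d)[2],
    lambda_max_nm = "lambda_max", f_N = "fraction_N", f_O = "fraction_O",
    deltaA_380 = "deltaA_380",
    rf_stop(paste("unrecognized observable column:", names(d)[2]), "format"))
  titration_curve(d[[1]], d[[2]], kind)
}

#' Write a fraction table CSV (`conc_mM,f_N,f_O,residual_sd`)
#'
#' @param fraction_table Data frame as returned by [fit_shared_bands()].
#' @param path File path.
#' @export
write_fraction_csv <- function(fraction_table, path) {
  ft <- as.data.frame(fraction_table)
  writeLines(c("conc_mM,f_N,f_O,residual_sd",
               paste(fmt17(ft$conc_mM), fmt17(ft$f_N), fmt17(ft$f_O),
                     fmt17(ft$residual_sd), sep = ",")),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_fraction_csv
#' @export
read_fraction_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("conc_mM", "f_N", "f_O") %in% names(d)))
    rf_stop("fraction CSV must have columns conc_mM,f_N,f_O", "format")
  d
}

#' Read and write a pigment band model as JSON
#'
#' Keys: `nu_max_cm1`, `amplitude`, `width_cm1`, `skew` for the main and
#' beta bands, plus `baseline_coeff`.
#'
#' @param model A [pigment_spectrum_model()].
#' @param path File path.
#' @export
write_band_json <- function(model, path) {
  stopifnot(inherits(model, "pigment_spectrum_model"))
  jsonlite::write_json(
    list(main_band = unclass(model$main_band),
         beta_band = unclass(model$beta_band),
         baseline_coeff = model$baseline_coeff),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_band_json
#' @export
read_band_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("main_band", "beta_band") %in% names(j)))
    rf_stop("band JSON must contain main_band and beta_band", "format")
  mk <- function(b) skewed_gaussian_band(b$nu_max_cm1, b$amplitude,
                                         b$width_cm1, b$skew)
  pigment_spectrum_model(mk(j$main_band), mk(j$beta_band),
                         if (is.null(j$baseline_coeff)) 0 else j$baseline_coeff)
}

#' Assemble a run report
#'
#' Collects the results of whichever analysis stages were run into one
#' summary object with a versioned machine-readable structure: the
#' photocycle time-constant table, state absorption maxima, uptake and
#' release dissociation constants with standard errors, their fold-ratio,
#' the Schiff-base pKa and the exponent-selection table. At least one
#' completed fit is required; rendering of partial result sets is
#' best-effort.
#'
#' @param global_fit Optional [fit_global()] result.
#' @param states Optional [reconstruct_states()] result.
#' @param hill_int Optional uptake `hill_fit` (from [fit_hill()]).
#' @param release Optional release `hill_fit` (from [release_constant()]).
#' @param pka Optional `pka_fit`.
#' @param selection Optional [select_n_exponents()] result.
#' @return Object of class `photocycle_report` (print method provided);
#'   serialize with [write_report_json()].
#' @export
photocycle_report <- function(global_fit = NULL, states = NULL,
                              hill_int = NULL, release = NULL, pka = NULL,
                              selection = NULL) {
  if (is.null(global_fit) && is.null(states) && is.null(hill_int) &&
      is.null(release) && is.null(pka) && is.null(selection))
    rf_stop("report needs at least one completed fit", "invalid")
  rep <- list(schema_version = "1.0", generated = format(Sys.time(), tz = "UTC"))
  if (!is.null(global_fit)) {
    rep$tau <- data.frame(component = seq_along(global_fit$tau_ms),
                          tau_ms = global_fit$tau_ms,
                          se_ms = global_fit$tau_se_ms)
    rep$residual_sd_dOD <- global_fit$residual_sd
  }
  if (!is.null(states))
    rep$state_lambda_max_nm <- c(P0 = lambda_max(states$p0),
                                 states$lambda_max_nm)
  kd <- list()
  if (!is.null(hill_int))
    kd$uptake <- list(Kd_mM = hill_int$Kd, se_mM = hill_int$se_Kd,
                      hill_n = hill_int$n, se_n = hill_int$se_n)
  if (!is.null(release))
    kd$release <- list(Kd_mM = release$Kd, se_mM = release$se_Kd,
                       hill_n = release$n, se_n = release$se_n)
  if (length(kd)) rep$dissociation_constants <- kd
  if (!is.null(hill_int) && !is.null(release))
    rep$fold_ratio <- release$Kd / hill_int$Kd
  else if (!is.null(release) && !is.null(release$fold_ratio))
    rep$fold_ratio <- release$fold_ratio
  if (!is.null(pka))
    rep$schiff_base_pKa <- list(pKa = pka$pKa, se = pka$se_pKa)
  if (!is.null(selection)) {
    rep$exponent_selection <- selection$table
    rep$n_exponents_selected <- selection$n_selected
  }
  structure(rep, class = "photocycle_report")
}

#' @export
print.photocycle_report <- function(x, ...) {
  cat("== Photocycle analysis report (schema", x$schema_version, ") ==\n")
  if (!is.null(x$n_exponents_selected))
    cat("exponents selected:", x$n_exponents_selected, "\n")
  if (!is.null(x$tau)) {
    cat("time constants:\n")
    print(transform(x$tau, tau_ms = signif(tau_ms, 4),
                    se_ms = signif(se_ms, 3)), row.names = FALSE)
  }
  if (!is.null(x$state_lambda_max_nm)) {
    cat("state absorption maxima (nm):\n")
    print(round(x$state_lambda_max_nm, 1))
  }
  if (!is.null(x$dissociation_constants)) {
    for (nm in names(x$dissociation_constants)) {
      k <- x$dissociation_constants[[nm]]
      cat(sprintf("Kd (%s): %.4g +/- %.2g mM (Hill n %.3g +/- %.2g)\n",
                  nm, k$Kd_mM, k$se_mM, k$hill_n, k$se_n))
    }
  }
  if (!is.null(x$fold_ratio))
    cat(sprintf("release/uptake fold-ratio: %.3g\n", x$fold_ratio))
  if (!is.null(x$schiff_base_pKa))
    cat(sprintf("Schiff-base pKa: %.3f +/- %.3f\n",
                x$schiff_base_pKa$pKa, x$schiff_base_pKa$se))
  invisible(x)
}

#' @rdname photocycle_report
#' @param report A `photocycle_report`.
#' @param path Output JSON path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "photocycle_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", force = TRUE)
  invisible(path)
}
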