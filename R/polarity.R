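#' Construct a solvent-polarity series
#'
#' Pairs of solvent relative permittivity and observed emission-peak
#' wavelength, used to relate a fluorophore's peak position to the polarity of
#' its environment.
#'
#' @param permittivity Relative permittivities (dimensionless, > 1), distinct.
#' @param peak_nm Peak emission wavelengths in nm.
#' @return An object of class `solvent_series`.
#' @export
solvent_series <- function(permittivity, peak_nm) {
  permittivity <- as.numeric(permittivity)
  peak_nm <- as.numeric(peak_nm)
  if (length(permittivity) != length(peak_nm))
    stop_validation("permittivity and peak_nm must have the same length")
  if (length(permittivity) < 1L)
    stop_validation("solvent series needs at least one entry")
  if (any(!is.finite(permittivity)) || any(permittivity <= 1))
    stop_validation("relative permittivities must be finite and > 1")
  if (anyDuplicated(permittivity))
    stop_validation("relative permittivities must be distinct")
  structure(list(permittivity = permittivity, peak_nm = peak_nm),
            class = "solvent_series")
}

#' Read a solvent series from CSV (`permittivity,peak_nm`)
#'
#' @param path Path to the CSV file.
#' @return A [solvent_series()].
#' @export
read_solvent_series <- function(path) {
  if (!file.exists(path))
    stop_validation(sprintf("solvent series file not found: %s", path))
  df <- utils::read.csv(path, header = TRUE)
  solvent_series(df[[1L]], df[[2L]])
}

#' Regress emission-peak wavelength on solvent relative permittivity
#'
#' Ordinary least-squares line of peak position (nm) on relative permittivity.
#' A positive slope quantifies the red shift in more polar environments
#' (equivalently, the blue shift as hydrophobicity increases); comparing a
#' protein-bound peak position to this calibration line indicates the
#' effective polarity of the binding environment.
#'
#' @param series A [solvent_series()] with at least 2 entries.
#' @return An object of class `polarity_fit`: list with `slope` (nm per
#'   permittivity unit), `intercept` (nm), `r_squared`, and the fitted
#'   permittivity `range`.
#' @export
fit_peak_vs_permittivity <- function(series) {
  stopifnot(inherits(series, "solvent_series"))
  if (length(series$permittivity) < 2L)
    stop_validation("need at least 2 solvents to fit a line")
  fit <- stats::lm(series$peak_nm ~ series$permittivity)
  ss_tot <- sum((series$peak_nm - mean(series$peak_nm))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = stats::coef(fit)[[2L]],
                 intercept = stats::coef(fit)[[1L]],
                 r_squared = r2,
                 range = range(series$permittivity),
                 n = length(series$permittivity)),
            class = "polarity_fit")
}

#' @export
print.polarity_fit <- function(x, ...) {
  cat(sprintf(
    "<polarity_fit> peak = %.4g + %.4g * (eps/eps0) nm, r^2 = %.3f (n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Predict a peak wavelength from a polarity calibration
#'
#' @param fit A `polarity_fit`.
#' @param permittivity Relative permittivity value(s). Values outside the
#'   fitted range trigger an extrapolation warning.
#' @return Predicted peak wavelength(s) in nm.
#' @export
predict_peak <- function(fit, permittivity) {
  stopifnot(inherits(fit, "polarity_fit"))
  if (any(permittivity < fit$range[1L] | permittivity > fit$range[2L]))
    warning(sprintf(
      "extrapolating outside the calibrated permittivity range [%.3g, %.3g]",
      fit$range[1L], fit$range[2L]))
  fit$slope * permittivity + fit$intercept
}
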