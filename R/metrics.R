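#' Total fluorescence of a spectrum
#'
#' Sum of all intensity values over the scan range, the intensity observable
#' plotted against protein concentration in a titration.
#'
#' @param spectrum An [emission_spectrum()].
#' @return Total fluorescence in a.u.
#' @export
total_fluorescence <- function(spectrum) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  sum(spectrum$intensity)
}

#' Peak emission wavelength
#'
#' Discrete argmax refined by the vertex of the parabola through the three
#' points around it, giving sub-grid precision on smooth bands. Ties between
#' equal discrete maxima are broken toward the lower wavelength. If the
#' maximum falls on a scan edge the edge wavelength is returned with a
#' warning, since no interior refinement is possible there.
#'
#' @param spectrum An [emission_spectrum()].
#' @return Peak wavelength in nm.
#' @export
peak_wavelength <- function(spectrum) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  y <- spectrum$intensity
  wl <- spectrum$wavelength
  n <- length(y)
  i <- which.max(y)  # first index on ties = lower wavelength
  if (i == 1L || i == n) {
    warning("intensity maximum at scan edge; returning edge wavelength")
    return(wl[i])
  }
  x1 <- wl[i - 1L]; x2 <- wl[i]; x3 <- wl[i + 1L]
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  # vertex of the parabola through three (possibly unevenly spaced) points
  denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
  a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
  b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
  if (a == 0) return(x2)  # locally flat top: keep the discrete maximum
  v <- -b / (2 * a)
  # keep the refinement inside the bracketing interval
  if (v < x1 || v > x3) x2 else v
}

#' Spectral centre of mass (mean emission wavenumber)
#'
#' The intensity-weighted mean emission wavenumber,
#' `sum(F_i * nu_i) / sum(F_i)` with `nu_i = 1e7 / lambda_i(nm)` in cm^-1.
#' A robust alternative to the peak wavelength for quantifying spectral
#' shifts: blue shifts increase the centre of mass.
#'
#' @param spectrum An [emission_spectrum()] with positive total intensity.
#' @return Centre of mass in cm^-1.
#' @export
center_of_mass <- function(spectrum) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  total <- sum(spectrum$intensity)
  if (total <= 0)
    stop_validation("centre of mass requires positive total intensity")
  nu <- 1e7 / spectrum$wavelength
  sum(spectrum$intensity * nu) / total
}

#' Intensity ratio between two emission wavelengths
#'
#' `F(num) / F(den)` with both intensities read at the nearest grid point
#' (no interpolation, matching instrument sampling). The 428/413 nm default
#' tracks the blue shift of the protein-bound OleA band: as intensity moves
#' toward 413 nm the ratio falls.
#'
#' @param spectrum An [emission_spectrum()].
#' @param num Numerator wavelength in nm (default 428).
#' @param den Denominator wavelength in nm (default 413); its intensity must
#'   be nonzero.
#' @return Dimensionless intensity ratio.
#' @export
wavelength_ratio <- function(spectrum, num = 428, den = 413) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelength
  for (w in c(num, den))
    if (w < wl[1L] || w > wl[length(wl)])
      stop_validation(sprintf("wavelength %.6g nm outside grid", w))
  fn <- spectrum$intensity[nearest_index(wl, num)]
  fd <- spectrum$intensity[nearest_index(wl, den)]
  if (fd == 0)
    stop_validation(sprintf("zero intensity at denominator wavelength %.6g nm",
                            den))
  fn / fd
}

metric_kinds <- c("peak_nm", "com_wavenumber", "ratio_428_413",
                  "total_fluorescence")

#' Evaluate a shift metric along a titration
#'
#' Computes one scalar observable per spectrum, paired with the protein
#' concentrations, in concentration order. The resulting trace is the input
#' to [fit_binding()].
#'
#' @param series A [titration_series()].
#' @param kind One of `"peak_nm"`, `"com_wavenumber"`, `"ratio_428_413"`,
#'   `"total_fluorescence"`.
#' @return An object of class `metric_trace`: list with `kind`, `conc`,
#'   `value`, `tetramer`.
#' @export
metric_trace <- function(series, kind = metric_kinds) {
  stopifnot(inherits(series, "titration_series"))
  kind <- match.arg(kind)
  f <- switch(kind,
              peak_nm = peak_wavelength,
              com_wavenumber = center_of_mass,
              ratio_428_413 = wavelength_ratio,
              total_fluorescence = total_fluorescence)
  value <- vapply(seq_along(series$conc), function(i) {
    tryCatch(f(series$spectra[[i]]), error = function(e) {
      stop_validation(sprintf("metric %s failed at concentration %.3g M: %s",
                              kind, series$conc[i], conditionMessage(e)))
    })
  }, numeric(1L))
  structure(list(kind = kind, conc = series$conc, value = value,
                 tetramer = series$tetramer),
            class = "metric_trace")
}

#' @export
print.metric_trace <- function(x, ...) {
  cat(sprintf("<metric_trace> %s, %d concentrations (%s convention)\n",
              x$kind, length(x$conc), if (x$tetramer) "tetramer" else "monomer"))
  print(utils::head(data.frame(conc_M = x$conc, value = x$value), 6L))
  if (length(x$conc) > 6L) cat("...\n")
  invisible(x)
}

#' Convert a metric trace between tetramer and monomer concentration units
#'
#' Tetramer-equivalent concentrations are multiplied by 4 to obtain
#' monomer-equivalent units (and conversely). The fitted dissociation constant
#' rescales by exactly the same factor.
#'
#' @param trace A `metric_trace`.
#' @param to `"monomer"` or `"tetramer"`.
#' @return The converted `metric_trace`.
#' @export
convert_concentration <- function(trace, to = c("monomer", "tetramer")) {
  stopifnot(inherits(trace, "metric_trace"))
  to <- match.arg(to)
  out <- trace
  if (to == "monomer" && trace$tetramer) {
    out$conc <- trace$conc * 4
    out$tetramer <- FALSE
  } else if (to == "tetramer" && !trace$tetramer) {
    out$conc <- trace$conc / 4
    out$tetramer <- TRUE
  }
  out
}

#' Write a metric trace to CSV (`conc_M,metric_value`)
#'
#' @param trace A `metric_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "metric_trace"))
  writeLines(c(sprintf("# metric: %s", trace$kind),
               "conc_M,metric_value",
               sprintf("%.6g,%.6g", trace$conc, trace$value)), path)
  invisible(path)
}
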