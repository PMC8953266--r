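#' Smoothing parameters for emission scans
#'
#' A sliding-window average followed by a Savitzky-Golay filter, the standard
#' preparation before taking second derivatives of tryptophan emission scans.
#' The defaults (15-point window for both stages, cubic Savitzky-Golay) reduce
#' noise while leaving band shape and overall intensity essentially unchanged.
#'
#' @param window Width of the moving average in points; odd, at least 3.
#' @param sg_order Savitzky-Golay polynomial order; must be less than
#'   `sg_window`.
#' @param sg_window Savitzky-Golay window width in points; odd.
#' @return An object of class `smoothing_spec`.
#' @export
smoothing_spec <- function(window = 15L, sg_order = 3L, sg_window = 15L) {
  window <- as.integer(window)
  sg_order <- as.integer(sg_order)
  sg_window <- as.integer(sg_window)
  if (window < 3L || window %% 2L == 0L)
    stop_validation("window must be an odd integer >= 3")
  if (sg_window < 3L || sg_window %% 2L == 0L)
    stop_validation("sg_window must be an odd integer >= 3")
  if (sg_order >= sg_window)
    stop_validation("sg_order must be smaller than sg_window")
  structure(list(window = window, sg_order = sg_order, sg_window = sg_window),
            class = "smoothing_spec")
}

#' Normalise a spectrum to its value at a reference wavelength
#'
#' Divides every intensity by the intensity at the grid point nearest the
#' reference wavelength, so the spectrum equals 1 there. Normalising titration
#' spectra at a wavelength near the isosbestic-like crossing (420 nm for the
#' OleA band) highlights emission shifts independently of intensity changes.
#'
#' @param spectrum An [emission_spectrum()].
#' @param reference Reference wavelength in nm; must lie within the grid range
#'   and have nonzero intensity.
#' @return A normalised [emission_spectrum()].
#' @export
normalize_at <- function(spectrum, reference = 420) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelength
  if (reference < wl[1L] || reference > wl[length(wl)])
    stop_validation(sprintf("reference %.6g nm outside grid [%.6g, %.6g]",
                            reference, wl[1L], wl[length(wl)]))
  i <- nearest_index(wl, reference)
  ref <- spectrum$intensity[i]
  if (ref == 0)
    stop_validation(sprintf("zero intensity at reference wavelength %.6g nm",
                            wl[i]))
  out <- spectrum
  out$intensity <- spectrum$intensity / ref
  out
}

#' Normalise a spectrum to unit peak intensity
#'
#' @param spectrum An [emission_spectrum()] with positive maximum intensity.
#' @return A spectrum whose maximum intensity is 1.
#' @export
normalize_peak <- function(spectrum) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  m <- max(spectrum$intensity)
  if (m <= 0)
    stop_validation("cannot peak-normalise: maximum intensity is not positive")
  out <- spectrum
  out$intensity <- spectrum$intensity / m
  out
}

# Moving average with symmetric shrinking windows at the scan edges, so no
# intensities are fabricated beyond the measured range.
moving_average <- function(y, window) {
  n <- length(y)
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(y))
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
  }
  out
}

#' Smooth an emission spectrum
#'
#' Applies a sliding-window average followed by a Savitzky-Golay filter, in
#' that order. Both stages are linear and preserve constants, so band shape
#' and mean intensity are essentially unchanged on band-shaped inputs.
#'
#' @param spectrum An [emission_spectrum()] longer than `spec$window`.
#' @param spec A [smoothing_spec()].
#' @return The smoothed [emission_spectrum()].
#' @export
smooth_spectrum <- function(spectrum, spec = smoothing_spec()) {
  stopifnot(inherits(spectrum, "emission_spectrum"),
            inherits(spec, "smoothing_spec"))
  n <- length(spectrum$wavelength)
  if (n <= spec$window)
    stop_validation(sprintf("spectrum (%d points) must be longer than window (%d)",
                            n, spec$window))
  if (n <= spec$sg_window)
    stop_validation(sprintf("spectrum (%d points) must be longer than sg_window (%d)",
                            n, spec$sg_window))
  y <- moving_average(spectrum$intensity, spec$window)
  y <- as.numeric(signal::sgolayfilt(y, p = spec$sg_order, n = spec$sg_window))
  out <- spectrum
  out$intensity <- y
  out
}

#' Second derivative of a spectrum with respect to wavelength
#'
#' Central second differences on a uniform grid; the two end points are filled
#' with the one-sided second difference of the three nearest points. Units of
#' the result are a.u./nm^2.
#'
#' @param spectrum An [emission_spectrum()] on a uniform grid with at least 5
#'   points.
#' @return An [emission_spectrum()] carrying d2F/dlambda2.
#' @export
second_derivative <- function(spectrum) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelength
  n <- length(wl)
  if (n < 5L)
    stop_validation("need at least 5 points for a second derivative")
  h <- diff(wl)
  if (max(h) - min(h) > 1e-8 * mean(h))
    stop_validation("second_derivative requires a uniform wavelength grid")
  h <- mean(h)
  y <- spectrum$intensity
  d2 <- numeric(n)
  d2[2:(n - 1L)] <- (y[1:(n - 2L)] - 2 * y[2:(n - 1L)] + y[3:n]) / h^2
  d2[1L] <- (y[1L] - 2 * y[2L] + y[3L]) / h^2
  d2[n] <- (y[n - 2L] - 2 * y[n - 1L] + y[n]) / h^2
  out <- spectrum
  out$intensity <- d2
  out
}

#' Locate the most negative local minima of a second-derivative spectrum
#'
#' In second-derivative analysis of tryptophan emission, band positions appear
#' as negative peaks. This returns the wavelengths of the `n` most negative
#' strict local minima, in ascending wavelength order.
#'
#' @param second_deriv An [emission_spectrum()] holding a second derivative
#'   (see [second_derivative()]).
#' @param n Number of minima requested (>= 1). If fewer exist, all found are
#'   returned with a warning.
#' @return Numeric vector of wavelengths (nm), ascending.
#' @export
find_negative_peaks <- function(second_deriv, n = 2L) {
  stopifnot(inherits(second_deriv, "emission_spectrum"))
  n <- as.integer(n)
  if (n < 1L) stop_validation("n must be >= 1")
  y <- second_deriv$intensity
  m <- length(y)
  idx <- which(y[2:(m - 1L)] < y[1:(m - 2L)] &
               y[2:(m - 1L)] < y[3:m] &
               y[2:(m - 1L)] < 0) + 1L
  if (length(idx) < n) {
    warning(sprintf("requested %d negative minima, found %d", n, length(idx)))
    keep <- idx
  } else {
    keep <- idx[order(y[idx])][seq_len(n)]
  }
  sort(second_deriv$wavelength[keep])
}
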