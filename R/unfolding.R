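# Gas constant, J/(mol K)
R_GAS <- 8.314

#' Two-state denaturation signal (Santoro-Bolen model)
#'
#' The observed spectroscopic signal of a two-state folding equilibrium with
#' linear native and unfolded baselines and a linear dependence of the
#' unfolding free energy on denaturant concentration:
#' \deqn{y(d) = \frac{(a_N + b_N d) + (a_U + b_U d) K(d)}{1 + K(d)},\quad
#'       K(d) = \exp\!\left(-\frac{\Delta G_{H_2O} - m d}{R T}\right)}
#' At the midpoint `Cm = dG / m` the equilibrium constant is 1 and, with flat
#' baselines, the signal is the baseline average.
#'
#' @param d Denaturant concentration(s) in M.
#' @param dG Unfolding free energy in water, J/mol.
#' @param m m-value, J/(mol M).
#' @param a_n,b_n Native baseline intercept (a.u.) and slope (a.u./M).
#' @param a_u,b_u Unfolded baseline intercept and slope.
#' @param temperature Temperature in K.
#' @return Signal value(s), a.u.
#' @export
santoro_bolen_signal <- function(d, dG, m, a_n = 1, b_n = 0, a_u = 0,
                                 b_u = 0, temperature = 298.15) {
  K <- exp(-(dG - m * d) / (R_GAS * temperature))
  ((a_n + b_n * d) + (a_u + b_u * d) * K) / (1 + K)
}

#' Fit a two-state unfolding curve by linear extrapolation
#'
#' Six-parameter nonlinear least-squares fit of [santoro_bolen_signal()] to a
#' denaturation curve, yielding the unfolding free energy in water
#' `dG_H2O` (J/mol), the m-value (J/(mol M)), both baselines, and the derived
#' midpoint `Cm = dG_H2O / m`. Initial values come from linear fits to the
#' pre- and post-transition points and a logit regression of the apparent
#' unfolded fraction.
#'
#' @param curve An [unfolding_curve()] with at least 8 points whose transition
#'   is bracketed by the denaturant range.
#' @param temperature Temperature in K; defaults to the curve's.
#' @return An object of class `unfolding_fit` with elements `dG_H2O`,
#'   `m_value`, `a_n`, `b_n`, `a_u`, `b_u`, `Cm`, `temperature`, `se`
#'   (standard errors), `residuals`, `fitted`.
#' @export
fit_unfolding <- function(curve, temperature = curve$temperature) {
  stopifnot(inherits(curve, "unfolding_curve"))
  d <- curve$denaturant
  y <- curve$signal
  n <- length(d)
  if (n < 8L)
    stop_validation("unfolding fit needs at least 8 denaturant points")
  if (stats::sd(y) == 0 || diff(range(y)) < 1e-12 * max(abs(y), 1))
    stop_validation("signal does not vary; nothing to fit")

  # baselines from the first and last few points
  k <- max(3L, n %/% 5L)
  fit_n <- stats::lm(y[seq_len(k)] ~ d[seq_len(k)])
  fit_u <- stats::lm(y[(n - k + 1L):n] ~ d[(n - k + 1L):n])
  a_n0 <- stats::coef(fit_n)[[1L]]; b_n0 <- stats::coef(fit_n)[[2L]]
  a_u0 <- stats::coef(fit_u)[[1L]]; b_u0 <- stats::coef(fit_u)[[2L]]

  # apparent unfolded fraction and logit regression for (dG, m) starts
  y_n <- a_n0 + b_n0 * d
  y_u <- a_u0 + b_u0 * d
  f <- (y_n - y) / (y_n - y_u)
  use <- is.finite(f) & f > 0.02 & f < 0.98
  RT <- R_GAS * temperature
  if (sum(use) >= 2L) {
    lin <- stats::lm(I(RT * log(f[use] / (1 - f[use]))) ~ d[use])
    m0 <- stats::coef(lin)[[2L]]
    dG0 <- -stats::coef(lin)[[1L]]
  } else {
    m0 <- NA_real_
  }
  if (!is.finite(m0) || m0 <= 0) {
    cm0 <- d[which.min(abs(y - (y_n + y_u) / 2))]
    m0 <- 5000
    dG0 <- m0 * cm0
  }
  cm0 <- dG0 / m0
  margin <- 0.1 * diff(range(d))
  if (cm0 <= min(d) - margin || cm0 >= max(d) + margin)
    stop_fit(sprintf(
      "transition midpoint estimate %.3g M not bracketed by the data (%.3g-%.3g M)",
      cm0, min(d), max(d)))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ santoro_bolen_signal(d, dG, m, a_n, b_n, a_u, b_u, temperature),
      start = list(dG = dG0, m = m0, a_n = a_n0, b_n = b_n0,
                   a_u = a_u0, b_u = b_u0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop_fit(sprintf("unfolding fit failed: %s",
                                         conditionMessage(e))))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 6L),
                                                     names(est)))
  if (est[["m"]] <= 0)
    stop_fit("fit converged to a non-positive m-value")
  Cm <- est[["dG"]] / est[["m"]]
  if (Cm <= min(d) - margin || Cm >= max(d) + margin)
    stop_fit(sprintf(
      "fitted midpoint Cm = %.3g M: transition not bracketed by the data (%.3g-%.3g M)",
      Cm, min(d), max(d)))
  if (Cm < min(d) || Cm > max(d))
    warning(sprintf("fitted midpoint Cm = %.3g M lies outside the measured range",
                    Cm))
  structure(list(
    dG_H2O = est[["dG"]], m_value = est[["m"]],
    a_n = est[["a_n"]], b_n = est[["b_n"]],
    a_u = est[["a_u"]], b_u = est[["b_u"]],
    Cm = Cm, temperature = temperature,
    se = c(dG_H2O = unname(se["dG"]), m_value = unname(se["m"]),
           a_n = unname(se["a_n"]), b_n = unname(se["b_n"]),
           a_u = unname(se["a_u"]), b_u = unname(se["b_u"])),
    residuals = as.numeric(y - stats::fitted(fit)),
    fitted = as.numeric(stats::fitted(fit)),
    denaturant = d, signal = y),
    class = "unfolding_fit")
}

#' @export
print.unfolding_fit <- function(x, ...) {
  cat("<unfolding_fit> two-state linear extrapolation\n")
  cat(sprintf("  dG_H2O = %.0f J/mol (SE %.0f)\n", x$dG_H2O, x$se[["dG_H2O"]]))
  cat(sprintf("  m      = %.0f J/(mol M) (SE %.0f)\n", x$m_value,
              x$se[["m_value"]]))
  cat(sprintf("  Cm     = %.3f M at T = %.2f K\n", x$Cm, x$temperature))
  invisible(x)
}

#' Stability change between two unfolding fits
#'
#' `holo$dG_H2O - apo$dG_H2O` with the standard error propagated in
#' quadrature. A positive value means the ligand-bound (holo) state is more
#' stable against denaturation.
#'
#' @param apo,holo `unfolding_fit` objects at the same temperature.
#' @return A list with `ddG` (J/mol) and `se`.
#' @export
delta_delta_g <- function(apo, holo) {
  stopifnot(inherits(apo, "unfolding_fit"), inherits(holo, "unfolding_fit"))
  if (abs(apo$temperature - holo$temperature) > 1e-6)
    stop_validation("unfolding fits were made at different temperatures")
  list(ddG = holo$dG_H2O - apo$dG_H2O,
       se = sqrt(apo$se[["dG_H2O"]]^2 + holo$se[["dG_H2O"]]^2))
}
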