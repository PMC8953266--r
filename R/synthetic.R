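# Synthetic-data generator
#
# Emulates the fluorescence experiments the analysis pipeline consumes: a
# ligand emission band whose centre moves from a free-ligand wavelength to a
# bound-ligand wavelength as a saturable function of protein concentration,
# an intensity rise containing both a saturable (specific) and a weak
# non-saturating (surface/nonspecific) component, Gaussian measurement noise,
# two-state urea-unfolding curves with linear baselines, and three-component
# excitation-emission matrices. Fixture constants are solved so that the
# noise-free observables reproduce the published scalar endpoints of the
# TTR/OleA titrations (peak shifts, constant M-TTR peak, total-fluorescence
# fold change).

titration_grid <- function() seq(400, 600, by = 1)
titration_concs <- function() 10^seq(-8, -4, length.out = 21L)

# Sum over the wavelength grid of a unit-amplitude Gaussian band centred at
# mu; this is what total_fluorescence sees, including truncation at the scan
# edges.
band_grid_sum <- function(mu, sigma, grid = titration_grid()) {
  sum(exp(-(grid - mu)^2 / (2 * sigma^2)))
}

# Given K_D and the observed peak positions at the two extreme
# concentrations, solve for the underlying free/bound band centres of the
# model centre(c) = lambda_free - (lambda_free - lambda_bound) * bf(c):
# a 2x2 linear system in (lambda_free, delta).
solve_lambda_endpoints <- function(kd, peak_lo, peak_hi,
                                   c_lo = 1e-8, c_hi = 1e-4) {
  bf_lo <- 1 / (1 + kd / c_lo)
  bf_hi <- 1 / (1 + kd / c_hi)
  delta <- (peak_lo - peak_hi) / (bf_hi - bf_lo)
  lambda_free <- peak_lo + delta * bf_lo
  list(lambda_free = lambda_free, lambda_bound = lambda_free - delta)
}

# Solve the nonspecific intensity gain a2 so that the summed (total)
# fluorescence ratio between the highest and lowest concentrations equals
# `ratio`. The grid sum of the band depends on its centre (the band is
# truncated at the scan edge), so the band coverage enters; the equation
# stays linear in a2.
solve_a2 <- function(kd, lambda_free, lambda_bound, a1, k2, ratio,
                     sigma = 25, c_lo = 1e-8, c_hi = 1e-4) {
  bf_lo <- 1 / (1 + kd / c_lo)
  bf_hi <- 1 / (1 + kd / c_hi)
  mu_lo <- lambda_free - (lambda_free - lambda_bound) * bf_lo
  mu_hi <- lambda_free - (lambda_free - lambda_bound) * bf_hi
  s_lo <- band_grid_sum(mu_lo, sigma)
  s_hi <- band_grid_sum(mu_hi, sigma)
  f_lo <- c_lo / (c_lo + k2)
  f_hi <- c_hi / (c_hi + k2)
  (ratio * s_lo * (1 + a1 * bf_lo) - s_hi * (1 + a1 * bf_hi)) /
    (s_hi * f_hi - ratio * s_lo * f_lo)
}

#' Built-in titration fixtures
#'
#' Named parameter sets driving [simulate_titration()], one per protein
#' variant of the TTR/OleA study:
#' \describe{
#'   \item{wt}{specific binding with `K_D = 3.23e-6` M; band centres solved so
#'     the noise-free peak moves 435 -> 413 nm across the concentration grid
#'     and the total-fluorescence fold change is 10.6.}
#'   \item{L55P}{`K_D = 3.12e-6` M with a much smaller shift
#'     (431.2 -> 425.2 nm), reflecting an altered binding pocket.}
#'   \item{M}{no specific binding (`K_D = Inf`): constant 426 nm peak, with
#'     only the weak nonspecific intensity term.}
#' }
#' All fixtures share the 400-600 nm grid (1 nm step), 21 log-spaced
#' tetramer concentrations from 1e-8 to 1e-4 M, a Gaussian band of sigma
#' 25 nm, and 2\% relative Gaussian noise by default.
#'
#' @return A named list of fixtures, each a list with elements `name`, `kd`,
#'   `lambda_free`, `lambda_bound`, `sigma`, `A0`, `a1`, `a2`, `k2`,
#'   `noise_sd`, `grid`, `conc`, `ligand_conc`.
#' @export
builtin_fixtures <- function() {
  grid <- titration_grid()
  conc <- titration_concs()
  a1 <- 4
  k2 <- 3e-4
  sigma <- 25

  wt_l <- solve_lambda_endpoints(3.23e-6, 435, 413)
  wt_a2 <- solve_a2(3.23e-6, wt_l$lambda_free, wt_l$lambda_bound,
                    a1, k2, ratio = 10.6, sigma = sigma)
  l55p_l <- solve_lambda_endpoints(3.12e-6, 431.2, 425.2)

  base <- list(sigma = sigma, A0 = 100, a1 = a1, a2 = wt_a2, k2 = k2,
               noise_sd = 0.02, grid = grid, conc = conc, ligand_conc = 5e-7)
  list(
    wt = c(list(name = "wt", kd = 3.23e-6,
                lambda_free = wt_l$lambda_free,
                lambda_bound = wt_l$lambda_bound), base),
    L55P = c(list(name = "L55P", kd = 3.12e-6,
                  lambda_free = l55p_l$lambda_free,
                  lambda_bound = l55p_l$lambda_bound), base),
    M = c(list(name = "M", kd = Inf,
               lambda_free = 426, lambda_bound = 426),
          utils::modifyList(base, list(a1 = 0)))
  )
}

#' Simulate a fluorescence titration
#'
#' For each protein concentration `c` the bound fraction is
#' `bf = 1 / (1 + K_D / c)` (zero when the fixture has no specific binding),
#' the band centre interpolates linearly in `bf` between the free and bound
#' wavelengths, and the amplitude is
#' `A0 * (1 + a1 * bf + a2 * c / (c + K2))` - a saturable specific gain plus
#' a weak nonspecific gain that does not plateau within the measured range.
#' Each spectrum is a Gaussian band on the fixture grid plus homoscedastic
#' Gaussian noise with standard deviation `noise_sd * A(c)`.
#'
#' @param fixture One element of [builtin_fixtures()] (or a list with the
#'   same fields).
#' @param seed Integer seed; the series is bit-identical for equal seeds.
#' @param noise_sd Override of the fixture's relative noise level (0 gives a
#'   noise-free series).
#' @return A [titration_series()].
#' @export
simulate_titration <- function(fixture, seed = 1L, noise_sd = fixture$noise_sd) {
  set.seed(as.integer(seed))
  grid <- fixture$grid
  spectra <- lapply(seq_along(fixture$conc), function(i) {
    c_ <- fixture$conc[i]
    bf <- if (is.finite(fixture$kd)) 1 / (1 + fixture$kd / c_) else 0
    mu <- fixture$lambda_free -
      (fixture$lambda_free - fixture$lambda_bound) * bf
    A <- fixture$A0 *
      (1 + fixture$a1 * bf + fixture$a2 * c_ / (c_ + fixture$k2))
    y <- A * exp(-(grid - mu)^2 / (2 * fixture$sigma^2))
    if (noise_sd > 0)
      y <- y + stats::rnorm(length(grid), sd = noise_sd * A)
    emission_spectrum(grid, y, excitation_nm = 340,
                      label = sprintf("%s %.3g M", fixture$name, c_))
  })
  titration_series(fixture$conc, spectra, ligand_conc = fixture$ligand_conc,
                   tetramer = TRUE)
}

#' Unfolding fixture
#'
#' Parameter set for [simulate_unfolding()]. Defaults: m-value 5000
#' J/(mol M), native baseline `1 - 0.01 d`, unfolded baseline
#' `0.3 - 0.005 d`, 17 urea points from 0 to 8 M, 298.15 K, absolute noise
#' sd 0.01 (1\% of the native signal). With the default m-value the
#' published unfolding free energies put the midpoint near 4-4.6 M urea,
#' comfortably bracketed by the grid.
#'
#' @param dG Unfolding free energy in water, J/mol.
#' @param m m-value, J/(mol M).
#' @param a_n,b_n,a_u,b_u Baseline parameters (a.u. and a.u./M).
#' @param denaturant Urea grid in M.
#' @param temperature Temperature in K.
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @return A list of class `unfolding_fixture`.
#' @export
unfolding_fixture <- function(dG = 21800, m = 5000, a_n = 1, b_n = -0.01,
                              a_u = 0.3, b_u = -0.005,
                              denaturant = seq(0, 8, length.out = 17L),
                              temperature = 298.15, noise_sd = 0.01) {
  if (dG <= 0 || m <= 0)
    stop_validation("dG and m must be positive")
  structure(list(dG = dG, m = m, a_n = a_n, b_n = b_n, a_u = a_u, b_u = b_u,
                 denaturant = denaturant, temperature = temperature,
                 noise_sd = noise_sd),
            class = "unfolding_fixture")
}

#' Built-in unfolding fixtures
#'
#' One fixture per protein/ligand state of the TTR study, differing only in
#' the generating unfolding free energy: wt 21800 (apo) / 22600 (holo), L55P
#' 23000 (apo) / 22800 (holo), M-TTR 20400 (apo) / 20200 (holo) J/mol.
#'
#' @return Named list of [unfolding_fixture()] objects (`wt_apo`, `wt_holo`,
#'   `L55P_apo`, `L55P_holo`, `M_apo`, `M_holo`).
#' @export
builtin_unfolding_fixtures <- function() {
  dgs <- c(wt_apo = 21800, wt_holo = 22600, L55P_apo = 23000,
           L55P_holo = 22800, M_apo = 20400, M_holo = 20200)
  lapply(dgs, function(dg) unfolding_fixture(dG = dg))
}

#' Simulate a urea-unfolding curve
#'
#' Evaluates [santoro_bolen_signal()] at each denaturant point of the fixture
#' and adds Gaussian noise. Deterministic for a given seed.
#'
#' @param fixture An [unfolding_fixture()].
#' @param seed Integer seed.
#' @param noise_sd Override of the fixture noise level.
#' @return An [unfolding_curve()].
#' @export
simulate_unfolding <- function(fixture, seed = 1L,
                               noise_sd = fixture$noise_sd) {
  stopifnot(inherits(fixture, "unfolding_fixture"))
  set.seed(as.integer(seed))
  y <- santoro_bolen_signal(fixture$denaturant, fixture$dG, fixture$m,
                            fixture$a_n, fixture$b_n, fixture$a_u,
                            fixture$b_u, fixture$temperature)
  if (noise_sd > 0)
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  unfolding_curve(fixture$denaturant, y, temperature = fixture$temperature)
}

#' Simulate an excitation-emission matrix
#'
#' Three idealised EEMs mirroring the qualitative structure of the ligand,
#' protein and complex measurements: the free ligand is essentially
#' non-fluorescent; the protein alone shows only intrinsic tryptophan
#' emission (band centred at 335 nm for excitation in the 280-310 nm range);
#' the complex additionally shows the ligand band centred near 420 nm,
#' excited around 340 nm.
#'
#' @param kind `"ligand_only"`, `"protein_only"` or `"complex"`.
#' @return An [eem_matrix()] on a 280-340 nm excitation grid (5 nm step) and
#'   300-600 nm emission grid (2 nm step).
#' @export
simulate_eem <- function(kind = c("ligand_only", "protein_only", "complex")) {
  kind <- match.arg(kind)
  ex <- seq(280, 340, by = 5)
  em <- seq(300, 600, by = 2)
  trp <- outer(exp(-(ex - 295)^2 / (2 * 10^2)),
               exp(-(em - 335)^2 / (2 * 15^2))) * 100
  lig <- outer(exp(-(ex - 340)^2 / (2 * 12^2)),
               exp(-(em - 420)^2 / (2 * 25^2))) * 60
  intensity <- switch(kind,
                      ligand_only = matrix(0.1, length(ex), length(em)),
                      protein_only = trp,
                      complex = trp + lig)
  eem_matrix(ex, em, intensity)
}
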