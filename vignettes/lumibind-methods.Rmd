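---
title: "Models and methods behind lumibind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lumibind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumibind)
```

`lumibind` analyses steady-state fluorescence experiments on protein–ligand
systems in which ligand binding is reported by an emission band that grows
and blue-shifts with binding. The motivating system is transthyretin (TTR),
a homotetrameric transport protein whose dissociation into monomers seeds
amyloid formation, and oleuropein aglycone (OleA), an olive polyphenol that
develops a 400–450 nm emission band upon complex formation. This vignette
explains each model in the package, the assumptions behind it, the numerical
choices made, and what the synthetic-data generator does and does not
emulate.

## Shift metrics

A titration records one emission scan per protein concentration at constant
ligand concentration. Four scalar observables summarise each scan:

* **Total fluorescence** — the plain sum of intensities over the scan range.
  It is homogeneous of degree 1 in intensity and tracks the overall
  emission rise.
* **Peak wavelength** — the discrete argmax refined by the vertex of a
  parabola through the three surrounding points. On a smooth band sampled
  at 1 nm this locates the centre to well under 0.1 nm. Ties between equal
  discrete maxima resolve to the lower wavelength; a maximum on a scan edge
  is returned as the edge wavelength with a warning, because no interior
  refinement exists there. If the three-point parabola is degenerate (flat
  top) the discrete maximum is kept, and a refined vertex falling outside
  its bracketing interval (possible only with pathological noise) is
  rejected in favour of the discrete maximum.
* **Centre of mass (COM)** — the intensity-weighted mean emission
  wavenumber, `sum(F_i * nu_i) / sum(F_i)` with `nu_i = 1e7 / lambda_i` in
  cm⁻¹. This is the conventional spectroscopic definition: it has units of
  wavenumber and increases under a blue shift. (The reciprocal form
  `sum(F_i) / sum(F_i * nu_i)` sometimes seen in print is dimensionally a
  1/wavenumber; for a narrow band the two are monotone transforms of one
  another, so the choice does not affect fraction-bound extraction.)
* **Intensity ratio** `F(428)/F(413)` — both intensities read at the
  nearest grid point, no interpolation, since the instrument sampled only
  at grid wavelengths. The ratio falls as emission weight moves toward
  413 nm.

Peak, COM and ratio are invariant under positive intensity scaling, so they
isolate the *shift* component of the signal from the *intensity* component;
the tests enforce these invariances on 1000 random spectra.

## Binding model

The metric trace `y(c)` is fitted to the 1:1 saturation isotherm

$$y(c) = M_\mathrm{free} + (M_\mathrm{bound} - M_\mathrm{free})\,
\mathrm{bf}(c), \qquad \mathrm{bf}(c) = \frac{1}{1 + K_D / c},$$

where `c` is the total protein concentration. Assumptions: a single class
of independent sites, the metric responds linearly in the bound fraction,
and free ligand is not depleted by binding. The last assumption is the
classic titration approximation; it is imperfect whenever the ligand
concentration is not far below `K_D` (0.5 µM ligand against a ~3 µM `K_D`
here). The package therefore keeps the saturation form as the primary,
literature-comparable model and offers the exact mass-balance quadratic as
`fit_binding(..., model = "depletion", ligand_conc = ...)`, clearly
labelled, for users who want the depletion-corrected constant.

Numerical choices:

* `K_D` is optimised as `log K_D`, keeping it positive and making steps
  multiplicative across the four decades a titration spans.
* Both endpoints are *fitted*, never taken from the observed extremes: the
  lowest and highest measured concentrations need not reach the asymptotes.
* Levenberg–Marquardt (via `minpack.lm`) is started twice — once from the
  trace extremes with `K_D` at the concentration nearest the metric
  midpoint, and once from the best point of a coarse 40-point profiled
  log-grid scan (at fixed `K_D` the endpoints enter linearly and are
  profiled out by ordinary least squares). The lower-RSS solution is kept.
  The second start matters: on noisy small-shift traces the least-squares
  surface is multimodal, and a single midpoint start can converge to a
  local minimum or start on a singular Jacobian.
* Weighting is uniform; the data provide no replicate variances.
* Concentrations are tetramer-equivalent by default;
  `convert_concentration()` moves a trace to monomer units, which rescales
  the fitted `K_D` by exactly 4 (a tested equivariance).

Standard errors default to the asymptotic ones from the fit;
`bootstrap_errors()` replaces them with residual-resampling bootstrap
errors, which make no linearisation assumption. The bootstrap is
deterministic given its seed.

## Two-state unfolding

Urea-denaturation curves are fitted to the two-state
linear-extrapolation signal with linear native and unfolded baselines
(`santoro_bolen_signal()`), a six-parameter model. Assumptions: exactly two
thermodynamic states at every urea concentration, free energy linear in
denaturant, and baselines linear over the measured range. The same
monomer-style two-state form is applied to tetrameric and monomeric
proteins alike — no tetramer-dissociation term — matching how such curves
are commonly analysed; `dG_H2O` is then an apparent stability in J/mol.

Initialisation is by construction rather than guesswork: lines through the
first and last fifth of the points give the baselines; the apparent
unfolded fraction is formed from them, points with fraction in
(0.02, 0.98) enter a logit regression whose slope and intercept give `m`
and `dG` starts. A midpoint estimate falling more than 10 % of the data
span outside the measured range aborts with a "transition not bracketed"
error before any nonlinear iteration, and the same check is re-applied to
the converged midpoint. `Cm = dG_H2O / m` holds exactly for every fit
result by definition. Temperature defaults to 298.15 K and is echoed in the
result so the RT used is never implicit.

Noise-free synthetic curves are recovered to four significant figures
across random admissible parameter sets (midpoints between 2.5 and 6 M on
the 0–8 M grid); this is a property test, not an assumption. At realistic
noise (sd 0.01 on a unit-scale signal, 17 points) the per-fit standard
error on `dG_H2O` is of order 1500–2000 J/mol even though the midpoint is
determined to ~0.1 %: `dG` and `m` are strongly correlated, and only their
ratio is sharply identified. Medians over many replicates are accordingly
the quantity the acceptance checks use.

## Solvent-polarity calibration

Peak position is regressed linearly on relative permittivity ε/ε₀ — the
model is phenomenological, chosen because peak-versus-permittivity is how
such data are plotted and compared; no orientation-polarizability
(Lippert–Mataga) treatment is attempted. Predictions outside the calibrated
permittivity range warn about extrapolation. With all-equal peaks the slope
is 0 and r² is defined as 0.

## Smoothing and second derivatives

Tryptophan emission scans are prepared for second-derivative band analysis
by a 15-point sliding-window average followed by a Savitzky–Golay filter
(order 3, window 15 — the order and window are free choices surfaced in
`smoothing_spec()`, defaulted to preserve band shape and overall
intensity). Edges of the moving average shrink symmetrically rather than
padding, so no intensities are fabricated beyond the scan. The second
derivative is a central second difference on a uniform grid with one-sided
ends; band positions then appear as negative local minima, extracted by
`find_negative_peaks()`.

Resolution has a hard limit: two Gaussian components are separable in the
second derivative only if they are narrow relative to their separation.
For the 330/350 nm tryptophan doublet used in the tests, components of
σ = 6 nm (FWHM ≈ 14 nm, typical of resolved tryptophan bands) produce two
clean minima within 2 nm of the true centres after the full
smooth–differentiate chain on a 0.5 nm scan step; components of σ = 12 nm
analytically produce only one minimum — the exact second derivative of
that doublet has a single negative extremum — so no peak-finder can report
two. The generator's doublet therefore uses σ = 6 nm.

## What the synthetic generator emulates — and what it does not

`simulate_titration()` draws, for each concentration, a Gaussian emission
band (σ = 25 nm on a 400–600 nm, 1 nm grid) whose centre interpolates
between the free and bound wavelengths in the bound fraction, with
amplitude `A0 (1 + a1·bf + a2·c/(c + K2))` — a saturable specific gain plus
a weak nonspecific gain (`K2 = 300 µM`) that keeps total intensity rising
without a plateau through 100 µM, consistent with a second, lower-affinity
surface interaction. Noise is homoscedastic Gaussian per point with sd
proportional (2 % by default) to the band amplitude.

The fixture constants are not free: band-centre endpoints are solved from
the observed extreme peaks through the binding equation (a 2×2 linear
solve), and the nonspecific gain `a2` is solved so the *summed* intensity
ratio between the extreme concentrations equals the published 10.6-fold
rise. That solve accounts for the band being truncated at the 400 nm scan
edge by different amounts at the two endpoint centres (grid coverage 0.92
at 435 nm versus 0.70 at 413 nm) — equating amplitude ratios instead would
misstate the summed ratio by ~25 %. The L55P and M fixtures reuse the
wild-type intensity parameters, as no variant-specific intensity data
exist to constrain them.

The generator does **not** emulate: Raman scatter or harmonic artifacts
(visible in real EEMs), inner-filter effects, photobleaching, wavelength-
dependent detector response, correlated noise, or any asymmetry of the real
emission band. Passing parameter-recovery tests therefore shows that the
inference pipeline is correct *under the stated noise model*, not that real
spectra meet that model. Raw per-figure spectra for the motivating study
are unpublished, so fixtures reproduce printed scalar summaries only; no
claim is made that simulated spectra match measured ones point for point.

Unfolding fixtures use m = 5000 J/(mol·M), native baseline `1 − 0.01 d`,
unfolded baseline `0.3 − 0.005 d`, 17 points over 0–8 M urea and absolute
noise sd 0.01. The m-value, baselines and grid are generator choices (the
source experiments report only the free energies); they are set so the six
published energies give midpoints near 4.0–4.6 M, well bracketed with
several points on each baseline, and all are exposed as
`unfolding_fixture()` arguments.

## Problem sizes and determinism

The recovery checks use 100 replicate titrations (21 spectra × 201 points
each) per binding fixture and 100 replicate curves per unfolding fixture;
the whole acceptance computation runs in a few seconds on one core, and the
test suite in under a minute. Every stochastic step flows from a single
integer seed with replicate *k* using `seed + k − 1`, so all reported
numbers are exactly reproducible.

## Known limitations

* The saturation isotherm ignores ligand depletion (see above); the
  depletion variant is provided but is not the primary model.
* A Hill or two-site model is deliberately absent: the motivating data
  include evidence of a second weak interaction, but no fitted equation for
  it, and the nonspecific intensity term in the generator is a
  data-generating device, not an inferential model.
* `dG_H2O` from single noisy unfolding curves carries large correlated
  uncertainty with `m`; report `Cm` alongside it, and prefer replicate
  medians for comparisons.
* The EEM simulator is a three-band cartoon intended for slicing and
  plumbing tests, not for spectral realism.
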