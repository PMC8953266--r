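# lumibind

Fluorescence-spectroscopy analysis of protein–ligand binding and stability,
built around the interaction between transthyretin (TTR) and oleuropein
aglycone (OleA), the deglycosylated main olive polyphenol. OleA is weakly
fluorescent when free in water but develops a strong emission band between
400 and 450 nm when bound to TTR, and that band shifts blue as binding
saturates. `lumibind` turns such spectra into quantitative binding and
stability parameters:

* **Spectra handling** — readers/writers and validated containers for
  emission scans, excitation–emission matrices (EEMs), titration series and
  urea-denaturation tables (all plain CSV).
* **Preprocessing** — blank subtraction, reference-wavelength and peak
  normalisation, sliding-window + Savitzky–Golay smoothing, second
  derivatives and negative-peak detection for resolving overlapping
  tryptophan bands.
* **Shift metrics** — peak wavelength (with sub-grid quadratic refinement),
  spectral centre of mass (mean emission wavenumber, cm⁻¹), the
  F(428)/F(413) intensity ratio, and total fluorescence, each traced along a
  titration.
* **Binding inference** — a shift-metric trace is fitted to the 1:1 isotherm

  ```
  y(c) = M_free + (M_bound − M_free) · bf(c),   bf(c) = 1 / (1 + K_D / c)
  ```

  by nonlinear least squares with K_D on a log scale, giving the
  dissociation constant, the free/bound metric endpoints, and
  residual-resampling bootstrap errors. An exact mass-balance (ligand
  depletion) variant is available via `model = "depletion"`.
* **Equilibrium unfolding** — Santoro–Bolen two-state linear-extrapolation
  fitting of denaturation curves,

  ```
  y(d) = [(a_N + b_N·d) + (a_U + b_U·d)·K(d)] / [1 + K(d)]
  K(d) = exp(−(ΔG_H2O − m·d) / RT)
  ```

  yielding ΔG_H2O (J/mol), the m-value, the baselines and the midpoint
  Cm = ΔG_H2O/m, plus ΔΔG between apo and holo fits.
* **Solvent-polarity calibration** — ordinary least squares of emission-peak
  position on solvent relative permittivity (ε/ε₀).
* **Synthetic data** — generators for titrations, unfolding curves and EEMs
  whose noise-free observables reproduce the published scalar endpoints of
  the TTR/OleA study (22 nm wild-type blue shift, 6 nm L55P shift, constant
  426 nm M-TTR peak, 10.6× intensity rise, K_D = 3.23/3.12 µM, the six
  unfolding free energies), so every stage of the pipeline is verifiable by
  parameter recovery.

## Worked example

Simulate one noisy wild-type titration, trace the emission peak, and fit the
binding isotherm:

```r
library(lumibind)

fx     <- builtin_fixtures()$wt
series <- simulate_titration(fx, seed = 1)          # 21 spectra, 1e-8..1e-4 M
trace  <- metric_trace(series, "peak_nm")
fit    <- fit_binding(trace)
fit    <- bootstrap_errors(trace, fit, n_boot = 200, seed = 1)
fit
#> <binding_fit> saturation model on peak_nm metric (tetramer concentrations)
#>   K_D     = 2.112e-06 M (SE 6.8e-07, bootstrap, n_boot = 200)
#>   M_free  = 436.385   M_bound = 414.739
#>   RMS residual = 2.46 over 21 points
```

This single replicate recovers K_D = 2.1 ± 0.7 µM against a generating value
of 3.23 µM: with 2 % spectral noise the peak-wavelength estimator is noisy,
and a single titration determines K_D only to within a factor of ~2 (the
bootstrap SE says as much). The median over 100 replicate titrations lands
at 3.09 µM. `M_free`/`M_bound` are the fitted peak-wavelength endpoints of
the free (≈435 nm) and bound (≈413 nm) ligand; `fraction_bound(trace, fit)`
rescales the trace between them.

Stability by urea unfolding, apo versus ligand-bound:

```r
ufx  <- builtin_unfolding_fixtures()
apo  <- fit_unfolding(simulate_unfolding(ufx$wt_apo,  seed = 1))
holo <- fit_unfolding(simulate_unfolding(ufx$wt_holo, seed = 1))
apo
#> <unfolding_fit> two-state linear extrapolation
#>   dG_H2O = 20423 J/mol (SE 1452)
#>   m      = 4647 J/(mol M) (SE 337)
#>   Cm     = 4.395 M at T = 298.15 K
delta_delta_g(apo, holo)$ddG
#> [1] 751.4305
```

Solvent-polarity calibration from the packaged water/1-butanol peak pair:

```r
cal <- fit_peak_vs_permittivity(
  read_solvent_series(system.file("extdata", "solvent_peaks.csv",
                                  package = "lumibind")))
cal
#> <polarity_fit> peak = 419.3 + 0.824 * (eps/eps0) nm, r^2 = 1.000 (n = 2)
predict_peak(cal, 80)     # water
#> [1] 485.2
```

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "lumibind.R", package = "lumibind")` with
`simulate-titration`, `simulate-unfolding`, `titrate`, `unfold`, `polarity`
and `eem-slice` subcommands.

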