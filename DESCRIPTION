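Package: lumibind
Title: Fluorescence Titration, Binding and Equilibrium-Unfolding Analysis for
    Protein-Ligand Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterise protein-ligand interactions from steady-state
    fluorescence spectroscopy, built around the transthyretin (TTR) and
    oleuropein-aglycone (OleA) system. Provides readers and containers for
    emission spectra, excitation-emission matrices, titration series and
    chemical-denaturation tables; spectral preprocessing (blank subtraction,
    normalisation, sliding-window and Savitzky-Golay smoothing, second
    derivatives); shift metrics (peak wavelength, spectral centre of mass,
    intensity ratios, total fluorescence); 1:1 binding-isotherm fitting of
    shift-metric traces with bootstrap errors; Santoro-Bolen two-state
    linear-extrapolation fitting of urea-unfolding curves; emission-peak
    versus solvent-permittivity regression; and a synthetic-data generator
    emulating the titration, unfolding and excitation-emission experiments so
    that every stage of the pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
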