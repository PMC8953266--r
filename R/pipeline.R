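# End-to-end pipeline runners. These are the programmatic entry points the
# command-line wrapper (inst/scripts/lumibind.R) calls; every defaulted
# parameter is echoed into the JSON result so a run is self-describing and
# reproducible.

#' Run the full titration pipeline
#'
#' Reads a titration manifest (or takes a ready [titration_series()]),
#' optionally subtracts a blank spectrum, computes the chosen shift metric at
#' every concentration, fits the 1:1 binding isotherm and bootstrap errors,
#' and optionally writes a JSON result plus a residual CSV.
#'
#' @param manifest Path to a manifest CSV (`protein_conc_M,spectrum_path`) or
#'   a [titration_series()].
#' @param ligand_conc Ligand concentration in M (stored in the series).
#' @param blank Optional path to a blank spectrum CSV subtracted from every
#'   spectrum.
#' @param metric Shift metric to trace (see [metric_trace()]).
#' @param model Binding model (see [fit_binding()]).
#' @param n_boot Bootstrap replicates for standard errors; 0 skips the
#'   bootstrap.
#' @param seed Integer seed for the bootstrap.
#' @param out_json,out_residuals Optional output paths.
#' @return A list with the `binding_fit`, the `metric_trace`, and the
#'   `report` list written to JSON. Invisible.
#' @export
run_titrate <- function(manifest, ligand_conc = 5e-7, blank = NULL,
                        metric = "peak_nm", model = "saturation",
                        n_boot = 200L, seed = 1L,
                        out_json = NULL, out_residuals = NULL) {
  series <- if (inherits(manifest, "titration_series")) manifest
            else read_titration_manifest(manifest, ligand_conc = ligand_conc)
  if (!is.null(blank)) {
    blank_spec <- read_spectrum(blank)
    series$spectra <- lapply(series$spectra, blank_subtract, blank = blank_spec)
  }
  trace <- metric_trace(series, metric)
  fit <- fit_binding(trace, model = model,
                     ligand_conc = if (model == "depletion")
                       series$ligand_conc else NULL)
  if (n_boot > 0L)
    fit <- bootstrap_errors(trace, fit, n_boot = n_boot, seed = seed)
  report <- list(
    schema_version = "1.0",
    command = "titrate",
    parameters = list(metric = metric, model = model, n_boot = n_boot,
                      seed = seed, ligand_conc_M = series$ligand_conc,
                      blank_subtracted = !is.null(blank),
                      concentration_convention =
                        if (series$tetramer) "tetramer" else "monomer"),
    result = list(K_D_M = fit$kd, K_D_se_M = unname(fit$se[["kd"]]),
                  M_free = fit$m_free, M_bound = fit$m_bound,
                  M_free_se = unname(fit$se[["m_free"]]),
                  M_bound_se = unname(fit$se[["m_bound"]]),
                  se_method = fit$se_method,
                  rms_residual = sqrt(mean(fit$residuals^2)),
                  n_concentrations = length(trace$conc)))
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(out_residuals))
    utils::write.csv(data.frame(conc_M = fit$conc, value = fit$value,
                                fitted = fit$fitted,
                                residual = fit$residuals),
                     out_residuals, row.names = FALSE)
  invisible(list(fit = fit, trace = trace, report = report))
}

#' Run the unfolding pipeline
#'
#' Fits a denaturation curve with [fit_unfolding()]; when a comparison curve
#' is supplied, fits both and reports the stability change
#' [delta_delta_g()] (comparison minus primary, i.e. holo minus apo when the
#' primary curve is the apo one).
#'
#' @param curve Path to a curve CSV (`urea_M,signal`) or an
#'   [unfolding_curve()].
#' @param temperature Temperature in K.
#' @param compare Optional second curve (path or object) to compare against.
#' @param out_json Optional JSON output path.
#' @return A list with the fit(s) and the `report` list. Invisible.
#' @export
run_unfold <- function(curve, temperature = 298.15, compare = NULL,
                       out_json = NULL) {
  load_curve <- function(x)
    if (inherits(x, "unfolding_curve")) x
    else read_unfolding_curve(x, temperature = temperature)
  apo <- load_curve(curve)
  fit <- fit_unfolding(apo, temperature = temperature)
  report <- list(
    schema_version = "1.0",
    command = "unfold",
    parameters = list(temperature_K = temperature,
                      n_points = length(apo$denaturant)),
    result = list(dG_H2O_J_mol = fit$dG_H2O,
                  dG_se_J_mol = unname(fit$se[["dG_H2O"]]),
                  m_value_J_mol_M = fit$m_value,
                  m_se = unname(fit$se[["m_value"]]),
                  Cm_M = fit$Cm))
  fits <- list(fit = fit)
  if (!is.null(compare)) {
    holo_fit <- fit_unfolding(load_curve(compare), temperature = temperature)
    dd <- delta_delta_g(fit, holo_fit)
    report$comparison <- list(dG_H2O_J_mol = holo_fit$dG_H2O,
                              dG_se_J_mol = unname(holo_fit$se[["dG_H2O"]]),
                              ddG_J_mol = dd$ddG, ddG_se_J_mol = dd$se)
    fits$compare_fit <- holo_fit
  }
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(c(fits, list(report = report)))
}
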