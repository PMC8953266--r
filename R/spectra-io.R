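#' Construct an emission spectrum
#'
#' The atom of all processing in lumibind: a single fluorescence emission scan
#' on an ascending wavelength grid, with optional acquisition metadata.
#'
#' @param wavelength Numeric vector of emission wavelengths in nm, strictly
#'   increasing.
#' @param intensity Numeric vector of fluorescence intensities (arbitrary
#'   units), same length as `wavelength`. All values must be finite; negative
#'   values are allowed (they arise legitimately after blank subtraction).
#' @param excitation_nm Excitation wavelength in nm (optional metadata).
#' @param slit_nm Excitation/emission slit widths in nm (optional).
#' @param temperature_C Acquisition temperature in degrees Celsius (optional).
#' @param label Free-text label for the scan.
#'
#' @return An object of class `emission_spectrum`: a list with elements
#'   `wavelength`, `intensity` and `meta`.
#' @export
#' @examples
#' s <- emission_spectrum(400:600, dnorm(400:600, 450, 25))
#' s
emission_spectrum <- function(wavelength, intensity, excitation_nm = NA_real_,
                              slit_nm = NA_real_, temperature_C = NA_real_,
                              label = "") {
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) != length(intensity))
    stop_validation("wavelength and intensity must have the same length")
  if (length(wavelength) < 1L)
    stop_validation("spectrum must contain at least one point")
  if (!all(is.finite(wavelength)))
    stop_validation("all wavelengths must be finite")
  if (!all(is.finite(intensity)))
    stop_validation("all intensities must be finite")
  if (is.unsorted(wavelength, strictly = TRUE))
    stop_validation("wavelengths must be strictly increasing")
  structure(
    list(wavelength = wavelength, intensity = intensity,
         meta = list(excitation_nm = excitation_nm, slit_nm = slit_nm,
                     temperature_C = temperature_C, label = label)),
    class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  n <- length(x$wavelength)
  cat(sprintf("<emission_spectrum> %d points, %.6g-%.6g nm", n,
              x$wavelength[1L], x$wavelength[n]))
  if (!is.na(x$meta$excitation_nm))
    cat(sprintf(", excitation %.6g nm", x$meta$excitation_nm))
  if (nzchar(x$meta$label)) cat(" [", x$meta$label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.emission_spectrum <- function(x) length(x$wavelength)

#' Read an emission spectrum from a two-column CSV file
#'
#' Expects one header line followed by numeric rows `wavelength_nm,intensity`.
#' Rows are re-sorted to ascending wavelength (with a warning) if needed.
#'
#' @param path Path to the CSV file.
#' @param label Label stored in the spectrum metadata; defaults to the file
#'   name.
#' @return An [emission_spectrum()].
#' @export
read_spectrum <- function(path, label = basename(path)) {
  if (!file.exists(path))
    stop_validation(sprintf("spectrum file not found: %s", path))
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L)
    stop_validation(sprintf("expected two columns in %s", path))
  wl <- suppressWarnings(as.numeric(df[[1L]]))
  fl <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(!is.finite(wl) | !is.finite(fl))
  if (length(bad) > 0L)
    stop_validation(sprintf("malformed or non-finite row in %s at data line %d",
                            path, bad[1L]))
  if (anyDuplicated(wl))
    stop_validation(sprintf("duplicate wavelength in %s", path))
  if (is.unsorted(wl, strictly = TRUE)) {
    warning(sprintf("wavelengths in %s were not ascending; re-sorted", path))
    o <- order(wl)
    wl <- wl[o]
    fl <- fl[o]
  }
  emission_spectrum(wl, fl, label = label)
}

#' Write an emission spectrum to a two-column CSV file
#'
#' Values are written with 6 significant digits so that write/read round-trips
#' are deterministic.
#'
#' @param spectrum An [emission_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  lines <- c("wavelength_nm,intensity",
             sprintf("%.6g,%.6g", spectrum$wavelength, spectrum$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Subtract a blank spectrum from a sample spectrum
#'
#' Pointwise subtraction of the blank-solution scan, as done before any metric
#' is computed. Negative results are retained, not clipped: clipping would bias
#' centre-of-mass and total-fluorescence statistics.
#'
#' @param sample,blank [emission_spectrum()] objects on identical wavelength
#'   grids.
#' @return An [emission_spectrum()] with the sample's metadata.
#' @export
blank_subtract <- function(sample, blank) {
  stopifnot(inherits(sample, "emission_spectrum"),
            inherits(blank, "emission_spectrum"))
  if (!isTRUE(all.equal(sample$wavelength, blank$wavelength)))
    stop_validation("sample and blank are on different wavelength grids")
  out <- sample
  out$intensity <- sample$intensity - blank$intensity
  out
}

#' Construct an excitation-emission matrix
#'
#' @param excitation Excitation wavelength grid (nm), strictly increasing.
#' @param emission Emission wavelength grid (nm), strictly increasing.
#' @param intensity Numeric matrix of fluorescence intensities with
#'   `length(excitation)` rows and `length(emission)` columns.
#' @return An object of class `eem_matrix`.
#' @export
eem_matrix <- function(excitation, emission, intensity) {
  excitation <- as.numeric(excitation)
  emission <- as.numeric(emission)
  intensity <- as.matrix(intensity)
  if (is.unsorted(excitation, strictly = TRUE))
    stop_validation("excitation grid must be strictly increasing")
  if (is.unsorted(emission, strictly = TRUE))
    stop_validation("emission grid must be strictly increasing")
  if (nrow(intensity) != length(excitation) ||
      ncol(intensity) != length(emission))
    stop_validation("intensity matrix dimensions do not match the grids")
  if (!all(is.finite(intensity)))
    stop_validation("all EEM intensities must be finite")
  structure(list(excitation = excitation, emission = emission,
                 intensity = intensity),
            class = "eem_matrix")
}

#' @export
print.eem_matrix <- function(x, ...) {
  cat(sprintf(
    "<eem_matrix> excitation %.6g-%.6g nm (%d) x emission %.6g-%.6g nm (%d)\n",
    min(x$excitation), max(x$excitation), length(x$excitation),
    min(x$emission), max(x$emission), length(x$emission)))
  invisible(x)
}

#' Read an excitation-emission matrix from CSV
#'
#' Layout: the first row holds the emission grid (first cell empty or a
#' label), the first column holds the excitation grid, the body holds
#' intensities.
#'
#' @param path Path to the CSV file.
#' @return An [eem_matrix()].
#' @export
read_eem <- function(path) {
  if (!file.exists(path))
    stop_validation(sprintf("EEM file not found: %s", path))
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character")
  em <- suppressWarnings(as.numeric(raw[1L, -1L]))
  ex <- suppressWarnings(as.numeric(raw[-1L, 1L]))
  body <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw[-1L, -1L])), nrow = nrow(raw) - 1L))
  if (!all(is.finite(em)) || !all(is.finite(ex)) || !all(is.finite(body)))
    stop_validation(sprintf("non-numeric entries in EEM file %s", path))
  eem_matrix(ex, em, body)
}

#' Write an excitation-emission matrix to CSV
#'
#' @param eem An [eem_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eem <- function(eem, path) {
  stopifnot(inherits(eem, "eem_matrix"))
  header <- paste(c("excitation_nm", sprintf("%.6g", eem$emission)),
                  collapse = ",")
  rows <- vapply(seq_along(eem$excitation), function(i) {
    paste(c(sprintf("%.6g", eem$excitation[i]),
            sprintf("%.6g", eem$intensity[i, ])), collapse = ",")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Extract the emission spectrum at one excitation wavelength from an EEM
#'
#' Returns the measured emission row at the grid point nearest to the requested
#' excitation (ties broken toward the lower wavelength); no interpolation is
#' performed, so the slice is always measured data. The actual excitation used
#' is recorded in the spectrum metadata.
#'
#' @param eem An [eem_matrix()].
#' @param excitation Requested excitation wavelength (nm); must lie within the
#'   excitation grid range.
#' @return An [emission_spectrum()].
#' @export
eem_emission_slice <- function(eem, excitation) {
  stopifnot(inherits(eem, "eem_matrix"))
  if (excitation < min(eem$excitation) || excitation > max(eem$excitation))
    stop_validation(sprintf(
      "excitation %.6g nm outside EEM grid range [%.6g, %.6g]",
      excitation, min(eem$excitation), max(eem$excitation)))
  i <- nearest_index(eem$excitation, excitation)
  emission_spectrum(eem$emission, eem$intensity[i, ],
                    excitation_nm = eem$excitation[i],
                    label = sprintf("EEM slice at %.6g nm", eem$excitation[i]))
}

# Index of the grid point nearest x; ties go to the lower wavelength.
nearest_index <- function(grid, x) {
  d <- abs(grid - x)
  which(d == min(d))[1L]
}

#' Construct a titration series
#'
#' An ordered set of emission spectra recorded at a fixed ligand concentration
#' and increasing protein concentrations, all on a shared wavelength grid.
#'
#' @param conc Protein concentrations in M, strictly increasing and positive;
#'   one per spectrum.
#' @param spectra List of [emission_spectrum()] objects, one per concentration,
#'   sharing one wavelength grid.
#' @param ligand_conc Ligand concentration in M (constant across the series).
#' @param tetramer Logical; `TRUE` (default) means concentrations count
#'   tetramers, `FALSE` means monomer-equivalent units.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(conc, spectra, ligand_conc = NA_real_,
                             tetramer = TRUE) {
  conc <- as.numeric(conc)
  if (any(conc <= 0))
    stop_validation("protein concentrations must be positive")
  if (is.unsorted(conc, strictly = TRUE))
    stop_validation("protein concentrations must be strictly increasing")
  if (length(spectra) != length(conc))
    stop_validation("need exactly one spectrum per concentration")
  if (!all(vapply(spectra, inherits, logical(1L), "emission_spectrum")))
    stop_validation("spectra must all be emission_spectrum objects")
  grid <- spectra[[1L]]$wavelength
  same <- vapply(spectra, function(s)
    isTRUE(all.equal(s$wavelength, grid)), logical(1L))
  if (!all(same))
    stop_validation("all spectra in a titration must share one wavelength grid")
  structure(list(conc = conc, spectra = spectra, ligand_conc = ligand_conc,
                 tetramer = tetramer),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %d spectra, [protein] %.3g-%.3g M (%s), [ligand] %.3g M\n",
    length(x$conc), min(x$conc), max(x$conc),
    if (x$tetramer) "tetramer" else "monomer", x$ligand_conc))
  invisible(x)
}

#' Read a titration series from a manifest CSV
#'
#' The manifest has columns `protein_conc_M,spectrum_path`; spectrum paths are
#' resolved relative to the manifest's directory unless absolute.
#'
#' @param path Path to the manifest CSV.
#' @param ligand_conc Ligand concentration in M.
#' @param tetramer Concentration convention flag (see [titration_series()]).
#' @return A [titration_series()].
#' @export
read_titration_manifest <- function(path, ligand_conc = NA_real_,
                                    tetramer = TRUE) {
  if (!file.exists(path))
    stop_validation(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  conc <- suppressWarnings(as.numeric(df[[1L]]))
  if (!all(is.finite(conc)))
    stop_validation(sprintf("non-numeric concentration in manifest %s", path))
  base <- dirname(path)
  files <- ifelse(grepl("^(/|[A-Za-z]:)", df[[2L]]), df[[2L]],
                  file.path(base, df[[2L]]))
  missing <- !file.exists(files)
  if (any(missing))
    stop_validation(sprintf("manifest row %d: spectrum file not found: %s",
                            which(missing)[1L], files[which(missing)[1L]]))
  o <- order(conc)
  spectra <- lapply(files[o], read_spectrum)
  titration_series(conc[o], spectra, ligand_conc = ligand_conc,
                   tetramer = tetramer)
}

#' Write a titration series as spectrum CSVs plus a manifest
#'
#' @param series A [titration_series()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_titration <- function(series, dir) {
  stopifnot(inherits(series, "titration_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("spectrum_%02d.csv", seq_along(series$conc))
  for (i in seq_along(series$conc))
    write_spectrum(series$spectra[[i]], file.path(dir, files[i]))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("protein_conc_M,spectrum_path",
               sprintf("%.6g,%s", series$conc, files)), manifest)
  invisible(manifest)
}

#' Construct a chemical-denaturation curve
#'
#' One scalar spectral observable per denaturant concentration, as collected in
#' a urea-induced equilibrium-unfolding experiment.
#'
#' @param denaturant Denaturant concentrations in M, non-negative and
#'   ascending.
#' @param signal Spectral observable (a.u.), one finite value per point.
#' @param temperature Temperature in K.
#' @return An object of class `unfolding_curve`.
#' @export
unfolding_curve <- function(denaturant, signal, temperature = 298.15) {
  denaturant <- as.numeric(denaturant)
  signal <- as.numeric(signal)
  if (length(denaturant) != length(signal))
    stop_validation("denaturant and signal must have the same length")
  if (any(denaturant < 0))
    stop_validation("denaturant concentrations must be non-negative")
  if (is.unsorted(denaturant, strictly = TRUE))
    stop_validation("denaturant concentrations must be strictly increasing")
  if (!all(is.finite(signal)))
    stop_validation("all signal values must be finite")
  if (!is.finite(temperature) || temperature <= 0)
    stop_validation("temperature must be positive (K)")
  structure(list(denaturant = denaturant, signal = signal,
                 temperature = temperature),
            class = "unfolding_curve")
}

#' @export
print.unfolding_curve <- function(x, ...) {
  cat(sprintf("<unfolding_curve> %d points, 0-%.3g M, T = %.2f K\n",
              length(x$denaturant), max(x$denaturant), x$temperature))
  invisible(x)
}

#' Read an unfolding curve from a two-column CSV (`urea_M,signal`)
#'
#' @param path Path to the CSV file.
#' @param temperature Temperature in K.
#' @return An [unfolding_curve()].
#' @export
read_unfolding_curve <- function(path, temperature = 298.15) {
  if (!file.exists(path))
    stop_validation(sprintf("unfolding curve file not found: %s", path))
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  if (nrow(df) == 0L)
    stop_validation(sprintf("empty unfolding curve file: %s", path))
  d <- suppressWarnings(as.numeric(df[[1L]]))
  y <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(!is.finite(d) | !is.finite(y))
  if (length(bad) > 0L)
    stop_validation(sprintf("malformed row in %s at data line %d", path,
                            bad[1L]))
  o <- order(d)
  unfolding_curve(d[o], y[o], temperature = temperature)
}

#' Write an unfolding curve to CSV
#'
#' @param curve An [unfolding_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unfolding_curve <- function(curve, path) {
  stopifnot(inherits(curve, "unfolding_curve"))
  writeLines(c("urea_M,signal",
               sprintf("%.6g,%.6g", curve$denaturant, curve$signal)), path)
  invisible(path)
}
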