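test_that("spectrum CSV reading validates and sorts input", {
  p <- write_tmp_csv(c("wavelength_nm,intensity", "400,1.0", "401,1.1"))
  s <- read_spectrum(p)
  expect_s3_class(s, "emission_spectrum")
  expect_equal(s$wavelength, c(400, 401))
  expect_equal(s$intensity, c(1.0, 1.1))

  pd <- write_tmp_csv(c("wavelength_nm,intensity", "401,1.1", "400,1.0"))
  expect_warning(sd <- read_spectrum(pd), "re-sorted")
  expect_equal(sd$wavelength, s$wavelength)
  expect_equal(sd$intensity, s$intensity)

  pn <- write_tmp_csv(c("wavelength_nm,intensity", "400,NaN", "401,1.1"))
  expect_error(read_spectrum(pn), "line 1",
               class = "lumibind_validation_error")
  pdup <- write_tmp_csv(c("wavelength_nm,intensity", "400,1", "400,2"))
  expect_error(read_spectrum(pdup), "duplicate",
               class = "lumibind_validation_error")
})

test_that("write/read round-trips are stable at the stored precision", {
  set.seed(11)
  s <- random_spectrum()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, p1)
  s1 <- read_spectrum(p1)
  write_spectrum(s1, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(read_spectrum(p2)$intensity, s1$intensity)
})

test_that("blank subtraction is pointwise and keeps negatives", {
  s <- emission_spectrum(c(400, 401), c(3, 3))
  b <- emission_spectrum(c(400, 401), c(1, 2))
  expect_equal(blank_subtract(s, b)$intensity, c(2, 1))
  expect_equal(blank_subtract(s, s)$intensity, c(0, 0))
  zero <- emission_spectrum(c(400, 401), c(0, 0))
  expect_equal(blank_subtract(s, zero)$intensity, s$intensity)
  # subtracting a blank and then its negation restores the sample exactly
  neg <- b
  neg$intensity <- -b$intensity
  expect_equal(blank_subtract(blank_subtract(s, b), neg)$intensity,
               s$intensity)
  # result may go negative and must be kept
  big <- emission_spectrum(c(400, 401), c(10, 10))
  expect_equal(blank_subtract(s, big)$intensity, c(-7, -7))
  off <- emission_spectrum(c(400, 402), c(1, 1))
  expect_error(blank_subtract(s, off), "grids",
               class = "lumibind_validation_error")
})

test_that("EEM slicing returns measured rows at the nearest excitation", {
  eem <- eem_matrix(c(340, 345), 400:410,
                    matrix(0, 2, 11))
  s <- eem_emission_slice(eem, 341)
  expect_equal(s$meta$excitation_nm, 340)  # nearest-point, not interpolation
  expect_equal(length(s), length(eem$emission))
  expect_true(all(s$intensity == 0))
  # ties break toward the lower excitation
  expect_equal(eem_emission_slice(eem, 342.5)$meta$excitation_nm, 340)
  expect_error(eem_emission_slice(eem, 360), "outside",
               class = "lumibind_validation_error")
})

test_that("EEM CSV round-trips preserve grids and intensities", {
  eem <- simulate_eem("complex")
  p <- withr::local_tempfile(fileext = ".csv")
  write_eem(eem, p)
  back <- read_eem(p)
  expect_equal(back$excitation, eem$excitation)
  expect_equal(back$emission, eem$emission)
  expect_equal(back$intensity, eem$intensity, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("titration manifests round-trip and name missing files", {
  fx <- builtin_fixtures()$wt
  series <- simulate_titration(fx, seed = 3)
  dir <- withr::local_tempdir()
  manifest <- write_titration(series, dir)
  back <- read_titration_manifest(manifest, ligand_conc = 5e-7)
  expect_equal(back$conc, series$conc, tolerance = 1e-5)
  expect_equal(back$spectra[[1]]$wavelength, series$spectra[[1]]$wavelength)
  expect_equal(back$spectra[[21]]$intensity, series$spectra[[21]]$intensity,
               tolerance = 1e-5)

  file.remove(file.path(dir, "spectrum_05.csv"))
  expect_error(read_titration_manifest(manifest), "row 5",
               class = "lumibind_validation_error")
})

test_that("titration series invariants are enforced", {
  s <- gaussian_spectrum(430)
  expect_error(titration_series(c(1e-6, 1e-6), list(s, s)),
               "strictly increasing", class = "lumibind_validation_error")
  expect_error(titration_series(c(-1e-6, 1e-6), list(s, s)),
               "positive", class = "lumibind_validation_error")
  other <- gaussian_spectrum(430, grid = 300:500)
  expect_error(titration_series(c(1e-7, 1e-6), list(s, other)),
               "grid", class = "lumibind_validation_error")
})

test_that("unfolding curve CSVs validate and round-trip", {
  cv <- simulate_unfolding(unfolding_fixture(), seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_unfolding_curve(cv, p)
  back <- read_unfolding_curve(p)
  expect_equal(back$denaturant, cv$denaturant)
  expect_equal(back$signal, cv$signal, tolerance = 1e-5)

  empty <- write_tmp_csv("urea_M,signal")
  expect_error(read_unfolding_curve(empty), "empty",
               class = "lumibind_validation_error")
  bad <- write_tmp_csv(c("urea_M,signal", "0,1", "1,abc"))
  expect_error(read_unfolding_curve(bad), "line 2",
               class = "lumibind_validation_error")
})
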