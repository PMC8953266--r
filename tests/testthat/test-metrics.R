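test_that("total fluorescence is the plain intensity sum", {
  expect_equal(total_fluorescence(emission_spectrum(c(400, 401), c(1.5, 2.5))),
               4.0)
  expect_equal(total_fluorescence(emission_spectrum(400:410, rep(0, 11))), 0)
})

test_that("peak wavelength refines the argmax and handles ties and edges", {
  g <- gaussian_spectrum(435)
  expect_lt(abs(peak_wavelength(g) - 435), 0.1)
  # off-grid centre recovered to sub-grid precision
  g2 <- gaussian_spectrum(434.4)
  expect_lt(abs(peak_wavelength(g2) - 434.4), 0.1)

  # equal discrete maxima: the lower wavelength wins
  wl <- 425:445
  y <- rep(0, 21)
  y[wl %in% c(429, 431, 439, 441)] <- 0.5
  y[wl %in% c(430, 440)] <- 1
  expect_equal(peak_wavelength(emission_spectrum(wl, y)), 430)

  ramp <- emission_spectrum(400:450, seq(0, 1, length.out = 51))
  expect_warning(pk <- peak_wavelength(ramp), "edge")
  expect_equal(pk, 450)
})

test_that("centre of mass matches hand-computed wavenumber averages", {
  delta <- emission_spectrum(c(410, 420, 430), c(0, 1, 0))
  expect_equal(center_of_mass(delta), 1e7 / 420)

  two <- emission_spectrum(c(400, 450), c(1, 1))
  expect_equal(center_of_mass(two), (1e7 / 400 + 1e7 / 450) / 2)
  expect_equal(center_of_mass(two), 23611.11, tolerance = 1e-6)

  z <- emission_spectrum(400:410, rep(0, 11))
  expect_error(center_of_mass(z), "positive",
               class = "lumibind_validation_error")
})

test_that("centre of mass agrees with a direct-summation oracle", {
  set.seed(99)
  for (i in 1:50) {
    s <- random_spectrum()
    num <- 0
    den <- 0
    for (j in seq_along(s$wavelength)) {  # independent brute-force loop
      num <- num + s$intensity[j] * 1e7 / s$wavelength[j]
      den <- den + s$intensity[j]
    }
    expect_lt(abs(center_of_mass(s) / (num / den) - 1), 0.005)
  }
})

test_that("shift metrics are scale invariant; total is degree-1 homogeneous", {
  set.seed(5)
  for (i in 1:25) {
    s <- random_spectrum()
    k <- stats::runif(1, 0.1, 20)
    ks <- s
    ks$intensity <- k * s$intensity
    expect_equal(peak_wavelength(ks), peak_wavelength(s))
    expect_equal(center_of_mass(ks), center_of_mass(s))
    expect_equal(wavelength_ratio(ks), wavelength_ratio(s))
    expect_equal(total_fluorescence(ks), k * total_fluorescence(s))
  }
})

test_that("wavelength ratio reads nearest grid points", {
  flat <- emission_spectrum(400:600, rep(2, 201))
  expect_equal(wavelength_ratio(flat), 1)
  # band centred midway between 413 and 428: symmetric, ratio 1
  sym <- gaussian_spectrum(420.5)
  expect_equal(wavelength_ratio(sym), 1)
  z <- emission_spectrum(400:600, c(rep(0, 14), rep(1, 187)))  # F(413) = 0
  expect_error(wavelength_ratio(z), "denominator",
               class = "lumibind_validation_error")
})

test_that("metric traces follow the titration in concentration order", {
  s <- gaussian_spectrum(430)
  same <- titration_series(10^seq(-8, -4, length.out = 6),
                           replicate(6, s, simplify = FALSE))
  tr <- metric_trace(same, "peak_nm")
  expect_equal(tr$conc, same$conc)
  expect_true(all(abs(tr$value - tr$value[1]) < 1e-12))

  fx <- builtin_fixtures()
  wt <- metric_trace(simulate_titration(fx$wt, seed = 1, noise_sd = 0),
                     "peak_nm")
  expect_equal(wt$value[1] - wt$value[21], 22.0, tolerance = 1e-3)
  # blue shift: peak trace is monotone non-increasing without noise
  expect_true(all(diff(wt$value) <= 1e-9))

  l55p <- metric_trace(simulate_titration(fx$L55P, seed = 1, noise_sd = 0),
                       "peak_nm")
  expect_equal(l55p$value[1] - l55p$value[21], 6.0, tolerance = 1e-3)

  ratio <- metric_trace(simulate_titration(fx$wt, seed = 1, noise_sd = 0),
                        "ratio_428_413")
  expect_true(all(diff(ratio$value) < 0))  # weight moves toward 413 nm

  com <- metric_trace(simulate_titration(fx$wt, seed = 1, noise_sd = 0),
                      "com_wavenumber")
  expect_true(all(diff(com$value) > 0))  # blue shift raises the mean wavenumber
})

test_that("metric errors identify the offending concentration", {
  zero <- emission_spectrum(400:600, rep(0, 201))
  ok <- gaussian_spectrum(430)
  series <- titration_series(c(1e-8, 1e-7, 1e-6, 1e-5, 1e-4),
                             list(ok, ok, zero, ok, ok))
  expect_error(metric_trace(series, "com_wavenumber"), "1e-06",
               class = "lumibind_validation_error")
})

test_that("tetramer/monomer conversion rescales concentrations by 4", {
  fx <- builtin_fixtures()$wt
  tr <- metric_trace(simulate_titration(fx, seed = 1, noise_sd = 0), "peak_nm")
  mono <- convert_concentration(tr, "monomer")
  expect_equal(mono$conc, tr$conc * 4)
  expect_false(mono$tetramer)
  expect_equal(convert_concentration(mono, "tetramer")$conc, tr$conc)
})
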