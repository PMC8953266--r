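# Fixtures built in code: analytic Gaussian bands and random band-shaped
# spectra used across the test files.

gaussian_spectrum <- function(center, sigma = 25, grid = 400:600, A = 1) {
  emission_spectrum(grid, A * exp(-(grid - center)^2 / (2 * sigma^2)))
}

# A random positive band-shaped spectrum (sum of 1-3 Gaussians plus offset).
random_spectrum <- function(grid = 400:600) {
  k <- sample(1:3, 1L)
  y <- rep(stats::runif(1, 0.01, 0.1), length(grid))
  for (i in seq_len(k)) {
    y <- y + stats::runif(1, 0.5, 2) *
      exp(-(grid - stats::runif(1, 410, 590))^2 / (2 * stats::runif(1, 8, 40)^2))
  }
  emission_spectrum(grid, y)
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
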