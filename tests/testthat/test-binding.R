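# Build a metric_trace directly from the saturation model, with optional
# Gaussian noise on the trace values.
model_trace <- function(kd, conc = 10^seq(-8, -4, length.out = 21),
                        m_free = 435, m_bound = 413, noise_sd = 0) {
  bf <- 1 / (1 + kd / conc)
  value <- m_free + (m_bound - m_free) * bf
  if (noise_sd > 0) value <- value + stats::rnorm(length(conc), sd = noise_sd)
  structure(list(kind = "peak_nm", conc = conc, value = value,
                 tetramer = TRUE),
            class = c("metric_trace"))
}

# Independent oracle: 1000 log-spaced K_D candidates with the endpoints
# profiled out by ordinary linear least squares at each candidate.
grid_search_kd <- function(trace, n_grid = 1000) {
  kds <- 10^seq(-9, -3, length.out = n_grid)
  rss <- vapply(kds, function(kd) {
    x <- 1 / (1 + kd / trace$conc)
    sum(stats::residuals(stats::lm(trace$value ~ x))^2)
  }, numeric(1))
  kds[which.min(rss)]
}

test_that("noise-free traces return the generating K_D", {
  tr <- model_trace(3.23e-6)
  fit <- fit_binding(tr)
  expect_lt(abs(fit$kd / 3.23e-6 - 1), 1e-4)
  expect_lt(abs(fit$m_free - 435), 1e-3)
  expect_lt(abs(fit$m_bound - 413), 1e-3)
  expect_equal(fit$residuals, rep(0, 21), tolerance = 1e-8)
})

test_that("the fitted isotherm passes through half-saturation at K_D", {
  set.seed(31)
  tr <- model_trace(2e-6, noise_sd = 0.5)
  fit <- fit_binding(tr)
  expect_equal(predict(fit, fit$kd), (fit$m_free + fit$m_bound) / 2)
  # monotone in concentration
  pred <- predict(fit, 10^seq(-8, -4, length.out = 50))
  expect_true(all(diff(pred) < 0))
})

test_that("fit agrees with the profiled grid-search oracle on noisy traces", {
  set.seed(12)
  for (i in 1:10) {
    kd <- 10^stats::runif(1, -6.5, -5)
    tr <- model_trace(kd, noise_sd = 0.4)
    fit <- fit_binding(tr)
    oracle <- grid_search_kd(tr)
    expect_lt(abs(fit$kd / oracle - 1), 0.01)
  }
})

test_that("median recovered K_D is unbiased at realistic trace noise", {
  set.seed(1)
  kds <- vapply(1:100, function(k) {
    # sd 0.02 on the bound fraction scale = 0.02 * 22 nm on the peak trace
    tr <- model_trace(3.23e-6, noise_sd = 0.02 * 22)
    fit_binding(tr)$kd
  }, numeric(1))
  expect_lt(abs(stats::median(kds) / 3.23e-6 - 1), 0.1)
})

test_that("K_D recovery stays within 2 bootstrap SEs across noise levels", {
  for (sd_bf in c(0.01, 0.02, 0.05)) {
    set.seed(1000 + round(sd_bf * 1000))
    kds <- vapply(1:15, function(k)
      fit_binding(model_trace(3e-6, noise_sd = sd_bf * 22))$kd, numeric(1))
    set.seed(2000 + round(sd_bf * 1000))
    tr <- model_trace(3e-6, noise_sd = sd_bf * 22)
    fit <- bootstrap_errors(tr, fit_binding(tr), n_boot = 100, seed = 4)
    expect_lt(abs(stats::median(kds) - 3e-6), 2 * fit$se[["kd"]] + 1e-12)
  }
})

test_that("tetramer to monomer conversion scales K_D by exactly 4", {
  set.seed(8)
  tr <- model_trace(3.23e-6, noise_sd = 0.3)
  mono <- convert_concentration(tr, "monomer")
  expect_equal(fit_binding(mono)$kd / fit_binding(tr)$kd, 4,
               tolerance = 1e-6)
})

test_that("fraction bound rescales between the fitted endpoints", {
  tr <- model_trace(3.23e-6)
  fit <- fit_binding(tr)
  bf <- fraction_bound(tr, fit)
  expect_true(all(bf >= 0 & bf <= 1))
  expect_equal(bf, 1 / (1 + 3.23e-6 / tr$conc), tolerance = 1e-4,
               ignore_attr = TRUE)

  # direct substitution: at 40 uM, bf = 1 / (1 + 3.23/40)
  tr40 <- model_trace(3.23e-6, conc = c(1e-8, 1e-7, 1e-6, 1e-5, 4e-5, 1e-4))
  fit40 <- fit_binding(tr40)
  bf40 <- fraction_bound(tr40, fit40)
  expect_equal(bf40[5], 1 / (1 + 3.23e-6 / 4e-5), tolerance = 1e-4,
               ignore_attr = TRUE)

  # endpoint value maps to 0, midpoint value to 0.5
  tr2 <- tr
  tr2$value <- c(fit$m_free, (fit$m_free + fit$m_bound) / 2,
                 tr$value[3:21])
  bf2 <- fraction_bound(tr2, fit)
  expect_equal(bf2[1], 0, ignore_attr = TRUE)
  expect_equal(bf2[2], 0.5, ignore_attr = TRUE)
})

test_that("fraction bound reports clamping and rejects flat fits", {
  set.seed(21)
  tr <- model_trace(3.23e-6, noise_sd = 1)
  fit <- fit_binding(tr)
  bf <- fraction_bound(tr, fit)
  expect_true(all(bf >= 0 & bf <= 1))
  expect_true(attr(bf, "n_clamped") >= 0)
  flat <- fit
  flat$m_bound <- flat$m_free
  expect_error(fraction_bound(tr, flat), "coincide",
               class = "lumibind_fit_error")
})

test_that("input contracts are enforced", {
  expect_error(fit_binding(model_trace(1e-6, conc = c(1e-6, 2e-6, 3e-6, 4e-6))),
               "at least 5", class = "lumibind_validation_error")
  narrow <- model_trace(1e-6, conc = seq(1e-6, 9e-6, length.out = 9))
  expect_error(fit_binding(narrow), "orders of magnitude",
               class = "lumibind_validation_error")
  tr <- model_trace(1e-6)
  expect_error(fit_binding(tr, model = "depletion"), "ligand_conc",
               class = "lumibind_validation_error")
})

test_that("bootstrap errors are deterministic and vanish for exact fits", {
  tr <- model_trace(3.23e-6)
  fit <- fit_binding(tr)
  b1 <- bootstrap_errors(tr, fit, n_boot = 60, seed = 7)
  expect_equal(unname(b1$se), c(0, 0, 0), tolerance = 1e-8)

  set.seed(14)
  trn <- model_trace(3.23e-6, noise_sd = 0.4)
  fitn <- fit_binding(trn)
  b2 <- bootstrap_errors(trn, fitn, n_boot = 80, seed = 42)
  b3 <- bootstrap_errors(trn, fitn, n_boot = 80, seed = 42)
  expect_identical(b2$se, b3$se)
  expect_true(b2$se[["kd"]] > 0)
  expect_warning(bootstrap_errors(trn, fitn, n_boot = 49, seed = 1),
                 "n_boot")
})

test_that("the depletion variant inverts its own mass-balance isotherm", {
  conc <- 10^seq(-8, -4, length.out = 21)
  kd <- 3.23e-6
  L <- 5e-7
  s <- conc + L + kd
  bf <- ((s - sqrt(s^2 - 4 * conc * L)) / 2) / L
  tr <- structure(list(kind = "peak_nm", conc = conc,
                       value = 435 - 22.78 * bf, tetramer = TRUE),
                  class = "metric_trace")
  fit <- fit_binding(tr, model = "depletion", ligand_conc = L)
  expect_lt(abs(fit$kd / kd - 1), 1e-4)
  # the saturation model applied to depletion data overestimates K_D
  expect_gt(fit_binding(tr)$kd, kd)
})
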