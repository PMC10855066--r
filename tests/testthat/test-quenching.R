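test_that("inner filter correction has the stated closed form", {
  expect_equal(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(100, 0.5, 0.5), 100 * 10^0.5)
  expect_equal(round(inner_filter_correct(100, 0.5, 0.5), 2), 316.23)
  expect_error(inner_filter_correct(100, -0.1, 0.2), class = "specbind_domain_error")
})

test_that("Stern-Volmer fit recovers a noise-free constant exactly with kq identity", {
  gt <- ground_truth(k_true = 1e4, f0_true = 900, noise_sd = 0)
  fit <- suppressWarnings(
    stern_volmer(gen_quench(gt, qconcs = seq(1e-5, 8e-5, by = 1e-5)))
  )
  expect_lt(abs(fit$ksv - 1e4) / 1e4, 1e-9)
  expect_identical(fit$kq, fit$ksv / fit$tau0)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)

  # fitting Stern-Volmer to log-linear data with n = 1 returns Ksv = Kb
  ll <- gen_quench(ground_truth(k_true = 2e5, n_true = 1, noise_sd = 0),
                   model = "log_linear")
  fit_ll <- suppressWarnings(stern_volmer(ll))
  expect_lt(abs(fit_ll$ksv - 2e5) / 2e5, 1e-9)
})

test_that("Stern-Volmer diagnostics: intercept warning and domain errors", {
  d <- tibble::tibble(titrant_conc = c(1e-6, 2e-6, 3e-6),
                      value = c(400, 310, 240))
  expect_warning(stern_volmer(d, f0 = 900), class = "specbind_diagnostic")
  expect_error(stern_volmer(tibble::tibble(titrant_conc = c(1e-6, 2e-6, 3e-6),
                                           value = c(400, -1, 240)), f0 = 900),
               class = "specbind_domain_error")
  expect_error(stern_volmer(d[1:2, ], f0 = 900), class = "specbind_validation_error")
})

test_that("tabulated quenching rate constants follow kq = Ksv/tau0 at tau0 = 6 ns", {
  expect_equal(kq_from_ksv(6.60e4), 11.0e12)
  expect_equal(kq_from_ksv(43.26e4), 72.10e12)
  expect_equal(round(kq_from_ksv(26.15e4) / 1e12, 2), 43.58)
})

test_that("quenching mechanism classification uses the diffusion limit", {
  expect_equal(quench_mechanism(11.0e12)$mechanism, "static")
  expect_equal(quench_mechanism(1e10)$mechanism, "dynamic")
  expect_equal(quench_mechanism(2e10)$mechanism, "indeterminate")

  tab <- tibble::tibble(temperature_k = c(297, 303, 308),
                        ksv = c(6.60e4, 4.94e4, 3.55e4))
  m <- quench_mechanism(11.0e12, fits_by_t = tab)
  expect_true(m$ksv_decreasing_with_t)
  expect_equal(m$mechanism, "static")
})

test_that("displacement percent exchange is correct, monotone and scale invariant", {
  f0 <- 500
  expect_equal(displacement(tibble::tibble(titrant_conc = 1e-6, value = f0),
                            f0 = f0)$percent_ex, 0)
  d <- displacement(tibble::tibble(titrant_conc = 1e-6, value = 0.7094 * f0),
                    f0 = f0)
  expect_equal(round(d$percent_ex, 2), 29.06)

  ff <- c(450, 420, 380, 350)
  d2 <- displacement(tibble::tibble(titrant_conc = (1:4) * 1e-6, value = ff), f0 = f0)
  expect_true(all(diff(d2$percent_ex) > 0))
  d3 <- displacement(tibble::tibble(titrant_conc = (1:4) * 1e-6, value = 7 * ff),
                     f0 = 7 * f0)
  expect_equal(d3$percent_ex, d2$percent_ex)
  expect_equal(attr(d3, "max_percent"), max(d2$percent_ex))
})

test_that("iodide protection reproduces tabulated reductions and is scale invariant", {
  expect_equal(round(ki_protection(33.77e3, 32.24e3)$reduction_percent, 1), 4.5)
  expect_equal(round(ki_protection(16.83e3, 9.39e3)$reduction_percent, 1), 44.2)
  expect_equal(ki_protection(5e3, 5e3)$reduction_percent, 0)
  expect_equal(ki_protection(33.77e3, 32.24e3)$classification, "groove_or_mixed")
  expect_equal(ki_protection(2e4, 1e4)$classification, "intercalation_protective")
  expect_equal(ki_protection(3.377, 3.224)$reduction_percent,
               ki_protection(33.77e3, 32.24e3)$reduction_percent)
})

test_that("ionic-strength trend classifies slope direction with significance", {
  conc <- seq(0, 0.112, length.out = 8)
  wiggle <- c(0.2, -0.1, 0.15, -0.2, 0.1, -0.15, 0.05, -0.05)
  up <- tibble::tibble(titrant_conc = conc,
                       value = 500 * (1 + 0.8 * conc) + wiggle)
  expect_equal(ionic_strength_trend(up, f0 = 500)$classification,
               "electrostatic_component")
  down <- tibble::tibble(titrant_conc = conc,
                         value = 500 * (1 - 0.8 * conc) + wiggle)
  expect_equal(ionic_strength_trend(down, f0 = 500)$classification,
               "no_electrostatic")
  flat <- tibble::tibble(titrant_conc = conc, value = 500 + wiggle)
  expect_equal(ionic_strength_trend(flat, f0 = 500)$classification, "flat")
  # noisy but trendless data should also be flat
  withr::with_seed(2, {
    noisy <- tibble::tibble(titrant_conc = conc,
                            value = 500 + rnorm(8, 0, 5))
  })
  expect_equal(ionic_strength_trend(noisy, f0 = 500)$classification, "flat")
})
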