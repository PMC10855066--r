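test_that("double-log fit recovers noise-free ground truth and keeps Kb = 10^logKb", {
  gt <- ground_truth(k_true = 1e5, n_true = 1.0, noise_sd = 0)
  fit <- suppressWarnings(double_log_fit(gen_quench(gt, model = "log_linear")))
  expect_lt(abs(fit$log_kb - 5.0), 1e-9)
  expect_lt(abs(fit$n - 1.0), 1e-9)
  expect_identical(fit$kb, 10^fit$log_kb)

  gt2 <- ground_truth(k_true = 4e9, n_true = 1.8, noise_sd = 0)
  fit2 <- suppressWarnings(
    double_log_fit(gen_quench(gt2, qconcs = seq(2e-6, 2e-5, by = 2e-6),
                              model = "log_linear"))
  )
  expect_lt(abs(fit2$n - 1.8), 1e-9)
  expect_lt(abs(fit2$log_kb - log10(4e9)) / log10(4e9), 1e-9)
})

test_that("double-log fit rejects F outside (0, F0) naming the point", {
  d <- tibble::tibble(titrant_conc = c(1e-6, 2e-6, 3e-6),
                      value = c(800, 950, 700))
  err <- expect_error(double_log_fit(d, f0 = 900), class = "specbind_domain_error")
  expect_match(conditionMessage(err), "2e-06")
})

test_that("van't Hoff fit recovers ground truth, limits and the two-point closed form", {
  gt <- ground_truth(dh_true = -100e3, ds_true = -250, noise_sd = 0)
  th <- suppressWarnings(vant_hoff(gen_vant_hoff(gt, temps = c(297, 303, 308))))
  expect_lt(abs(th$dh - (-100e3)) / 100e3, 1e-9)
  expect_lt(abs(th$ds - (-250)) / 250, 1e-9)

  # Kb constant over T: dH = 0, dS = R ln(Kb)
  flat <- suppressWarnings(
    vant_hoff(tibble::tibble(temperature_k = c(297, 303, 308), kb = rep(2e4, 3)))
  )
  expect_equal(flat$dh, 0, tolerance = 1e-6)
  expect_equal(flat$ds, 8.314 * log(2e4), tolerance = 1e-9)

  # two points match the closed-form solution
  two <- tibble::tibble(temperature_k = c(297, 308), kb = c(3.09e4, 0.31e4))
  th2 <- suppressWarnings(vant_hoff(two))
  oracle <- vant_hoff_two_point(297, 3.09e4, 308, 0.31e4)
  expect_equal(th2$dh, oracle$dh, tolerance = 1e-9)
  expect_equal(th2$ds, oracle$ds, tolerance = 1e-9)

  expect_error(vant_hoff(tibble::tibble(temperature_k = c(297, 297), kb = c(1e4, 2e4))),
               class = "specbind_validation_error")
  expect_error(vant_hoff(tibble::tibble(temperature_k = c(297, 308), kb = c(1e4, -2))),
               class = "specbind_domain_error")
})

test_that("dG(T) always equals dH - T dS on a thermo fit", {
  for (seed in 1:5) {
    gt <- ground_truth(dh_true = -90e3, ds_true = -200, noise_sd = 0.02,
                       seed = seed)
    th <- vant_hoff(gen_vant_hoff(gt))
    expect_equal(th$dg_by_t$dg,
                 th$dh - th$dg_by_t$temperature_k * th$ds,
                 tolerance = 1e-12)
  }
})

test_that("gibbs_report evaluates both routes at the lowest temperature", {
  th <- suppressWarnings(vant_hoff(tibble::tibble(
    temperature_k = c(297, 303, 308),
    kb = c(3.09e4, 1.26e4, 0.31e4)
  )))
  rep_h <- gibbs_report(th, policy = "from_enthalpy")
  expect_equal(rep_h$temperature_k, 297)
  expect_equal(rep_h$dg, rep_h$dg_from_enthalpy)
  expect_equal(rep_h$dg_from_enthalpy, th$dh - 297 * th$ds, tolerance = 1e-12)
  rep_k <- gibbs_report(th, policy = "from_k")
  expect_equal(rep_k$dg, gibbs_from_k(3.09e4, 297))

  # printed-style reference pairs: dH - T dS at 297 K
  expect_equal(round((-93.87e3 - 297 * (-236.03)) / 1e3, 2), -23.77)
  expect_equal(round((-54.02e3 - 297 * (-67.01)) / 1e3, 2), -34.12)

  # dS = 0: dG = dH at any temperature
  th0 <- suppressWarnings(vant_hoff(tibble::tibble(
    temperature_k = c(297, 308),
    kb = exp(50e3 / (8.314 * c(297, 308)) * -1)
  )))
  expect_equal(gibbs_report(th0)$dg, th0$dh, tolerance = 1e-6)
})

test_that("interaction force rules follow the thermodynamic signatures", {
  expect_equal(interaction_forces(-155.65e3, -432.83), "hbond_vdw")
  expect_equal(interaction_forces(10e3, 50), "hydrophobic")
  expect_equal(interaction_forces(-1e3, 50), "electrostatic")
  expect_equal(interaction_forces(-50e3, 100), "mixed")
  expect_equal(interaction_forces(c(-155.65e3, 10e3), c(-432.83, 50)),
               c("hbond_vdw", "hydrophobic"))
})
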