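test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(spectrum(c(300, 310), c(1, 2)), "spectrum")
  expect_error(spectrum(c(310, 300), c(1, 2)), class = "specbind_validation_error")
  expect_error(spectrum(c(300, 300), c(1, 2)), class = "specbind_validation_error")
  expect_error(spectrum(300, 1), class = "specbind_validation_error")
  expect_error(spectrum(c(300, 310), c(1, 2, 3)), class = "specbind_validation_error")
  expect_error(spectrum(c(300, 310), c(-0.1, 0.2), mode = "absorbance"),
               class = "specbind_domain_error")
  # fluorescence may legitimately carry slightly negative noise
  expect_silent(spectrum(c(300, 310), c(-0.1, 0.2), mode = "fluorescence"))
})

test_that("titration_series validates ordering, temperature and shared grid", {
  base <- spectrum(c(600, 603, 606), c(80, 100, 90))
  pt <- function(wl, y) spectrum(wl, y)
  pts <- tibble::tibble(titrant_conc = c(1e-6, 2e-6),
                        spectrum = list(pt(c(600, 603, 606), c(70, 90, 80)),
                                        pt(c(600, 603, 606), c(60, 80, 70))))
  s <- titration_series(base, pts, assay = "eb_displacement")
  expect_equal(s$points$titrant_conc, c(1e-6, 2e-6))

  bad_order <- pts[2:1, ]
  expect_error(titration_series(base, bad_order), class = "specbind_validation_error")
  expect_error(titration_series(base, pts, temperature_k = -1),
               class = "specbind_validation_error")
  off_grid <- tibble::tibble(titrant_conc = 1e-6,
                             spectrum = list(pt(c(600, 604, 606), c(70, 90, 80))))
  expect_error(titration_series(base, off_grid), class = "specbind_grid_error")
})

test_that("read_series long layout preserves concentration order and ignores row order", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_toy_long_csv(f)
  s <- read_series(f, layout = "long", assay = "eb_displacement")
  expect_equal(s$points$titrant_conc, c(1e-6, 2e-6))
  expect_equal(attr(readout_at(s), "base_value"), 100)

  f2 <- withr::local_tempfile(fileext = ".csv")
  withr::with_seed(42, write_toy_long_csv(f2, shuffle = TRUE))
  s2 <- read_series(f2, layout = "long", assay = "eb_displacement")
  expect_equal(as_tibble(s2), as_tibble(s))
})

test_that("read_series rejects ragged grids and non-numeric cells with a row number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("titrant_conc,wavelength,intensity",
               "0,600,80", "0,603,100",
               "1e-6,600,70", "1e-6,610,90"), f)
  expect_error(read_series(f, layout = "long"), class = "specbind_grid_error")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("titrant_conc,wavelength,intensity",
               "0,600,80", "0,603,abc",
               "1e-6,600,70", "1e-6,603,60"), f3)
  err <- expect_error(read_series(f3, layout = "long"),
                      class = "specbind_parse_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "abc")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("titrant_conc,wavelength,intensity",
               "0,600,80", "0,603,100",
               "1e-6,600,70", "1e-6,603,60",
               "1e-6,600,71", "1e-6,603,61"), f4)
  expect_error(read_series(f4, layout = "long"), class = "specbind_grid_error")

  f5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("titrant_conc,wavelength,intensity",
               "1e-6,600,70", "1e-6,603,60"), f5)
  expect_error(read_series(f5, layout = "long"), class = "specbind_validation_error")
})

test_that("write/read round trip is value-identical on both layouts and JSON", {
  s <- gen_quench(ground_truth(k_true = 1e5, noise_sd = 0.01, seed = 7))
  for (layout in c("long", "wide")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_series(s, f, layout = layout)
    s2 <- read_series(f, layout = layout, mode = "fluorescence",
                      assay = "protein_quench")
    expect_equal(as_tibble(s2), as_tibble(s), tolerance = 1e-12)
  }
  fj <- withr::local_tempfile(fileext = ".json")
  write_series_json(s, fj)
  s3 <- read_series_json(fj)
  expect_equal(as_tibble(s3), as_tibble(s))
  expect_equal(s3$temperature_k, s$temperature_k)
  expect_equal(s3$assay, s$assay)
})

test_that("readout_at picks the base peak inside the window and holds it fixed", {
  wl <- seq(550, 650, by = 1)
  base_y <- exp(-((wl - 603)^2) / 200)
  # quenched spectra peak-shifted on purpose: channel must not follow them
  pt_y <- 0.5 * exp(-((wl - 620)^2) / 200)
  s <- titration_series(
    spectrum(wl, base_y),
    tibble::tibble(titrant_conc = 1e-6, spectrum = list(spectrum(wl, pt_y))),
    assay = "eb_displacement"
  )
  r <- readout_at(s, readout_policy("peak_max", window = c(550, 650)))
  expect_equal(attr(r, "wavelength_nm"), 603)
  expect_equal(r$value, 0.5 * exp(-((603 - 620)^2) / 200))

  # flat base spectrum: leftmost channel of the window (documented tie-break)
  s_flat <- titration_series(
    spectrum(wl, rep(1, length(wl))),
    tibble::tibble(titrant_conc = 1e-6,
                   spectrum = list(spectrum(wl, rep(0.5, length(wl))))),
    assay = "eb_displacement"
  )
  r_flat <- readout_at(s_flat, readout_policy("peak_max", window = c(560, 640)))
  expect_equal(attr(r_flat, "wavelength_nm"), 560)

  r_fix <- readout_at(s, readout_policy("fixed_wavelength", wavelength_nm = 580))
  expect_equal(attr(r_fix, "wavelength_nm"), 580)
  expect_equal(r_fix$value, pt_y[wl == 580])

  expect_error(readout_at(s, readout_policy("peak_max", window = c(500, 700))),
               class = "specbind_range_error")
  expect_error(readout_at(s, readout_policy("fixed_wavelength", wavelength_nm = 580.5)),
               class = "specbind_range_error")
})

test_that("readout is invariant to channels outside the readout window", {
  wl_small <- seq(580, 620, by = 2)
  wl_big <- seq(500, 700, by = 2)
  shape <- function(wl) exp(-((wl - 603)^2) / 150)
  mk <- function(wl) titration_series(
    spectrum(wl, shape(wl)),
    tibble::tibble(titrant_conc = c(1e-6, 2e-6),
                   spectrum = list(spectrum(wl, 0.8 * shape(wl)),
                                   spectrum(wl, 0.6 * shape(wl)))),
    assay = "eb_displacement"
  )
  pol <- readout_policy("peak_max", window = c(580, 620))
  expect_equal(readout_at(mk(wl_small), pol)$value,
               readout_at(mk(wl_big), pol)$value)
})
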