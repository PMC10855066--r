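#' Ground truth for synthetic titration data
#'
#' Collects the true parameters from which synthetic series are generated, so
#' that every downstream estimator can be tested by parameter recovery. The
#' same object parameterizes all four generators; each uses the fields it
#' needs.
#'
#' Defaults mirror the laboratory conditions the package targets: a ligand
#' band around 330-340 nm, hyperchromic complexation (`ac_true > a0_true`),
#' binding constants of the order seen for groove binders and plasma-protein
#' complexes, exothermic binding with negative entropy (hydrogen bonds / van
#' der Waals contacts), and 1% photometric noise.
#'
#' @param k_true True association / quenching / binding constant (1/M).
#' @param n_true True number of binding sites (log-linear quench law).
#' @param a0_true,ac_true True peak absorbance of the free ligand and of the
#'   fully complexed ligand.
#' @param f0_true True peak fluorescence of the unquenched fluorophore
#'   (arbitrary units).
#' @param dh_true,ds_true True binding enthalpy (J/mol) and entropy
#'   (J/(mol K)).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   base signal (`a0_true` or `f0_true`); `0` disables noise.
#' @param seed Integer seed fixing all randomness of the generators.
#' @return A `ground_truth` object (named list).
#' @export
ground_truth <- function(k_true = 5e3, n_true = 1,
                         a0_true = 0.85, ac_true = 1.25, f0_true = 900,
                         dh_true = -100e3, ds_true = -250,
                         noise_sd = 0.01, seed = 1L) {
  if (k_true <= 0) stop_domain("`k_true` must be > 0.")
  if (n_true <= 0) stop_domain("`n_true` must be > 0.")
  if (noise_sd < 0) stop_domain("`noise_sd` must be >= 0.")
  if (a0_true <= 0) stop_domain("`a0_true` must be > 0.")
  structure(list(k_true = k_true, n_true = n_true,
                 a0_true = a0_true, ac_true = ac_true, f0_true = f0_true,
                 dh_true = dh_true, ds_true = ds_true,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

# Gaussian band shape used for the decorative channels; only the peak channel
# carries the physically modelled value.
band_shape <- function(grid, center, width) exp(-((grid - center)^2) / (2 * width^2))

make_band_spectrum <- function(peak_value, grid, center, width, mode, noise_sd_abs) {
  y <- peak_value * band_shape(grid, center, width)
  if (noise_sd_abs > 0) y <- y + rnorm(length(grid), 0, noise_sd_abs)
  if (mode == "absorbance") y <- pmax(y, 0)  # physical non-negativity
  spectrum(grid, y, mode = mode)
}

#' Generate a synthetic UV-Vis DNA titration
#'
#' The peak-channel absorbance follows a 1:1 complexation isotherm: the bound
#' fraction is `alpha = K c / (1 + K c)` and the observed absorbance is
#' `A(c) = (1 - alpha) A0 + alpha Ac`, with seeded additive Gaussian noise of
#' standard deviation `noise_sd * a0_true` on every channel. The base
#' spectrum carries `a0_true` at the peak. The default titrant range
#' (12.5-75 uM) corresponds to DNA molar ratios 0.25-1.5 over a 50 uM ligand.
#'
#' @param gt A [ground_truth()].
#' @param concs Titrant (DNA) concentrations, mol/L, positive increasing.
#' @param grid,center,width Wavelength grid and band shape (nm).
#' @return A [titration_series()] with `assay = "uvvis_dna"`, ground truth
#'   attached in `$meta$ground_truth`.
#' @examples
#' s <- gen_uvvis(ground_truth(noise_sd = 0))
#' benesi_hildebrand(s)  # recovers k_true
#' @export
gen_uvvis <- function(gt, concs = seq(12.5e-6, 75e-6, by = 12.5e-6),
                      grid = seq(250, 450, by = 5), center = 330, width = 30) {
  stopifnot(inherits(gt, "ground_truth"))
  if (any(concs <= 0) || any(diff(concs) <= 0)) {
    stop_validation("`concs` must be positive and increasing.")
  }
  sd_abs <- gt$noise_sd * gt$a0_true
  withr::with_seed(gt$seed, {
    base <- make_band_spectrum(gt$a0_true, grid, center, width, "absorbance", sd_abs)
    specs <- purrr::map(concs, function(cc) {
      alpha <- gt$k_true * cc / (1 + gt$k_true * cc)
      a_obs <- (1 - alpha) * gt$a0_true + alpha * gt$ac_true
      make_band_spectrum(a_obs, grid, center, width, "absorbance", sd_abs)
    })
  })
  titration_series(
    base = base,
    points = tibble::tibble(titrant_conc = concs, spectrum = specs),
    temperature_k = 297, assay = "uvvis_dna",
    meta = list(ground_truth = unclass(gt), model = "one_to_one_isotherm")
  )
}

#' Generate a synthetic fluorescence quenching titration
#'
#' Two ground-truth laws are available:
#' * `"stern_volmer"`: `F = F0 / (1 + Ksv [Q])`, the law linearized by
#'   [stern_volmer()];
#' * `"log_linear"`: `(F0 - F)/F = Kb [Q]^n`, i.e.
#'   `F = F0 / (1 + Kb [Q]^n)`, the law linearized exactly by
#'   [double_log_fit()]. With `n = 1` the two laws coincide.
#'
#' The generating model is recorded in `$meta$quench_model` so a test can
#' never fit the wrong law silently. Noise is seeded additive Gaussian with
#' standard deviation `noise_sd * f0_true` on every channel.
#'
#' @param gt A [ground_truth()]; `k_true` is Ksv or Kb, `n_true` the
#'   log-linear exponent.
#' @param qconcs Quencher concentrations, mol/L, positive increasing. The
#'   default (0.2-2.0 uM) corresponds to ligand:protein molar ratios 0.2-2.0
#'   over a 1.0 uM protein.
#' @param model `"stern_volmer"` or `"log_linear"`.
#' @param assay Assay role recorded on the series.
#' @param temperature_k Temperature in kelvin.
#' @param grid,center,width Wavelength grid and emission band shape (nm).
#' @return A [titration_series()].
#' @export
gen_quench <- function(gt, qconcs = seq(2e-7, 2e-6, by = 2e-7),
                       model = c("stern_volmer", "log_linear"),
                       assay = "protein_quench", temperature_k = 297,
                       grid = seq(300, 500, by = 5), center = 340, width = 35) {
  stopifnot(inherits(gt, "ground_truth"))
  model <- match.arg(model)
  if (any(qconcs <= 0) || any(diff(qconcs) <= 0)) {
    stop_validation("`qconcs` must be positive and increasing.")
  }
  f_of <- function(q) {
    switch(model,
      stern_volmer = gt$f0_true / (1 + gt$k_true * q),
      log_linear = gt$f0_true / (1 + gt$k_true * q^gt$n_true)
    )
  }
  sd_abs <- gt$noise_sd * gt$f0_true
  withr::with_seed(gt$seed, {
    base <- make_band_spectrum(gt$f0_true, grid, center, width, "fluorescence", sd_abs)
    specs <- purrr::map(qconcs, function(q) {
      make_band_spectrum(f_of(q), grid, center, width, "fluorescence", sd_abs)
    })
  })
  titration_series(
    base = base,
    points = tibble::tibble(titrant_conc = qconcs, spectrum = specs),
    temperature_k = temperature_k, assay = assay,
    meta = list(ground_truth = unclass(gt), quench_model = model)
  )
}

#' Apply a synthetic inner filter effect to a series
#'
#' Attenuates every titration-point spectrum by `10^(-(A_ex + A_em)/2)` —
#' the observed, inner-filtered signal — and attaches the per-point
#' absorbances to the series so that [inner_filter_correct()] can undo the
#' attenuation exactly (inverse pair).
#'
#' @param series A fluorescence [titration_series()].
#' @param a_ex,a_em Absorbance at the excitation / emission wavelength, one
#'   value per titration point (recycled if scalar). Must be >= 0.
#' @return The attenuated series; `$points` gains columns `a_ex` and `a_em`.
#' @export
gen_inner_filter <- function(series, a_ex, a_em) {
  stopifnot(is_titration_series(series))
  n <- nrow(series$points)
  a_ex <- rep_len(a_ex, n); a_em <- rep_len(a_em, n)
  if (any(a_ex < 0) || any(a_em < 0)) stop_domain("Absorbances must be >= 0.")
  atten <- 10^(-(a_ex + a_em) / 2)
  series$points$spectrum <- purrr::map2(series$points$spectrum, atten, function(sp, k) {
    spectrum(sp$wavelength, sp$intensity * k, mode = spectrum_mode(sp))
  })
  series$points$a_ex <- a_ex
  series$points$a_em <- a_em
  series$meta$inner_filtered <- TRUE
  series
}

#' Generate equilibrium constants with van't Hoff temperature dependence
#'
#' `Kb(T) = exp(-dH/(R T) + dS/R)` with `R = 8.314` J/(mol K). When
#' `noise_sd > 0`, seeded multiplicative Gaussian noise `(1 + e)`,
#' `e ~ N(0, noise_sd)`, is applied to each constant (noise proportional to
#' signal, consistent with the intensity-noise convention of the other
#' generators).
#'
#' @param gt A [ground_truth()] supplying `dh_true`, `ds_true`.
#' @param temps Temperatures in kelvin; default the three assay temperatures
#'   297, 303 and 308 K.
#' @return A tibble with columns `temperature_k` and `kb`.
#' @examples
#' vant_hoff(gen_vant_hoff(ground_truth(noise_sd = 0)))
#' @export
gen_vant_hoff <- function(gt, temps = c(297, 303, 308)) {
  stopifnot(inherits(gt, "ground_truth"))
  if (any(temps <= 0)) stop_validation("Temperatures must be positive kelvin.")
  kb <- exp(-gt$dh_true / (R_GAS * temps) + gt$ds_true / R_GAS)
  if (gt$noise_sd > 0) {
    kb <- withr::with_seed(gt$seed, kb * (1 + rnorm(length(temps), 0, gt$noise_sd)))
  }
  tibble::tibble(temperature_k = as.numeric(temps), kb = kb)
}
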