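#' Inner filter effect correction
#'
#' Re-amplifies an observed fluorescence signal attenuated by sample
#' absorbance at the excitation and emission wavelengths:
#' `F = F_obs * 10^((A_ex + A_em)/2)`. Exact inverse of the attenuation
#' applied by [gen_inner_filter()].
#'
#' @param f_obs Observed fluorescence, or a [titration_series()] whose points
#'   carry `a_ex`/`a_em` columns (as attached by [gen_inner_filter()]).
#' @param a_ex,a_em Absorbance at the excitation / emission wavelength
#'   (>= 0). Ignored for series input. If a series carries no stored
#'   absorbances it is returned unchanged with a notice, since inventing
#'   absorbances would bias every downstream constant.
#' @return Corrected fluorescence values, or the corrected series.
#' @examples
#' inner_filter_correct(100, 0.5, 0.5)  # 316.23
#' @export
inner_filter_correct <- function(f_obs, a_ex = NULL, a_em = NULL) {
  UseMethod("inner_filter_correct")
}

#' @export
inner_filter_correct.default <- function(f_obs, a_ex = NULL, a_em = NULL) {
  if (is.null(a_ex) || is.null(a_em)) stop_validation("`a_ex` and `a_em` are required.")
  if (any(a_ex < 0) || any(a_em < 0)) stop_domain("Absorbances must be >= 0.")
  f_obs * 10^((a_ex + a_em) / 2)
}

#' @export
inner_filter_correct.titration_series <- function(f_obs, a_ex = NULL, a_em = NULL) {
  series <- f_obs
  if (!all(c("a_ex", "a_em") %in% names(series$points))) {
    message("No per-point excitation/emission absorbances on this series; inner filter correction skipped.")
    return(series)
  }
  amp <- 10^((series$points$a_ex + series$points$a_em) / 2)
  series$points$spectrum <- purrr::map2(series$points$spectrum, amp, function(sp, k) {
    spectrum(sp$wavelength, sp$intensity * k, mode = spectrum_mode(sp))
  })
  series$meta$inner_filtered <- FALSE
  series
}

#' Quenching rate constant from a Stern-Volmer constant
#'
#' `kq = Ksv / tau0`, with `tau0` the average fluorescence lifetime of the
#' biomolecule (6 ns for the plasma proteins analyzed here).
#'
#' @param ksv Stern-Volmer constant, 1/M.
#' @param tau0 Fluorophore lifetime in seconds (default 6e-9).
#' @return Bimolecular quenching rate constant, 1/(M s).
#' @export
kq_from_ksv <- function(ksv, tau0 = 6e-9) {
  if (any(tau0 <= 0)) stop_domain("`tau0` must be > 0.")
  ksv / tau0
}

#' Stern-Volmer quenching fit
#'
#' OLS of `F0/F` on the quencher concentration: `F0/F = 1 + Ksv [Q]`. The
#' slope is the Stern-Volmer constant and `kq = Ksv/tau0` the bimolecular
#' quenching rate constant. The intercept is fitted, not forced to 1; a
#' deviation of more than 10% from 1 raises a diagnostics warning. Inputs
#' are expected to be inner-filter-corrected already (see
#' [inner_filter_correct()]).
#'
#' @param data A data frame of readouts or a [titration_series()].
#' @param conc,f Column names holding quencher concentration (mol/L) and
#'   fluorescence.
#' @param f0 Unquenched fluorescence (> 0); for series input taken from the
#'   base spectrum.
#' @param tau0 Fluorophore lifetime in seconds (default 6 ns).
#' @param ... Passed to methods (`policy` for series input).
#' @return A `quench_fit`: fields `ksv`, `kq`, `tau0`, `intercept`, `r2`,
#'   `stderr_ksv`, `temperature_k` (if known). Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @examples
#' s <- gen_quench(ground_truth(k_true = 1e5, noise_sd = 0))
#' stern_volmer(s)
#' @export
stern_volmer <- function(data, ...) UseMethod("stern_volmer")

#' @rdname stern_volmer
#' @export
stern_volmer.titration_series <- function(data, ..., tau0 = 6e-9,
                                          policy = readout_policy()) {
  r <- readout_at(data, policy)
  out <- stern_volmer(r, conc = "titrant_conc", f = "value",
                      f0 = attr(r, "base_value"), tau0 = tau0)
  out$temperature_k <- data$temperature_k
  out
}

#' @rdname stern_volmer
#' @export
stern_volmer.data.frame <- function(data, conc = "titrant_conc", f = "value",
                                    f0, tau0 = 6e-9, ...) {
  q <- data[[conc]]
  ff <- data[[f]]
  if (length(q) < 3) stop_validation("Stern-Volmer needs at least 3 points.")
  if (f0 <= 0) stop_domain("`f0` must be > 0.")
  if (any(ff <= 0)) stop_domain("All fluorescence values must be > 0.")
  if (tau0 <= 0) stop_domain("`tau0` must be > 0.")
  y <- f0 / ff
  fit <- lm(y ~ q)
  b <- coef(fit)
  ksv <- b[[2]]
  if (abs(b[[1]] - 1) > 0.1) {
    warn(sprintf("Stern-Volmer intercept %.3f deviates more than 10%% from 1; check F0 and linear range.", b[[1]]),
         class = "specbind_diagnostic")
  }
  structure(list(
    ksv = ksv, kq = ksv / tau0, tau0 = tau0,
    intercept = b[[1]], r2 = summary(fit)$r.squared,
    stderr_ksv = summary(fit)$coefficients[2, 2],
    f0 = f0, n_points = length(q), temperature_k = NA_real_,
    data = tibble::tibble(conc = q, f = ff, y = y),
    lm = fit
  ), class = "quench_fit")
}

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf("<Stern-Volmer fit: Ksv = %.4g 1/M (se %.2g), kq = %.4g 1/(M s), intercept = %.3f, r2 = %.4f>\n",
              x$ksv, x$stderr_ksv, x$kq, x$intercept, x$r2))
  invisible(x)
}

#' Classify the quenching mechanism
#'
#' The diffusion-controlled limit for dynamic quenching in aqueous solution
#' is `kq = 2e10` 1/(M s); an apparent `kq` above it implies ground-state
#' complex formation (static quenching). A Stern-Volmer constant that falls
#' with rising temperature strengthens (but is not required for) the static
#' call; the temperature trend is reported alongside.
#'
#' @param fit A `quench_fit`, or a numeric `kq` in 1/(M s).
#' @param fits_by_t Optional list of `quench_fit`s at different temperatures
#'   (or a data frame with `temperature_k`, `ksv`) used to report the
#'   temperature trend.
#' @param dynamic_limit Diffusion limit (default 2e10).
#' @return A tibble with columns `kq`, `mechanism`
#'   (`"static"`/`"dynamic"`/`"indeterminate"`) and `ksv_decreasing_with_t`
#'   (`NA` when no multi-temperature evidence is given).
#' @export
quench_mechanism <- function(fit, fits_by_t = NULL, dynamic_limit = 2e10) {
  kq <- if (inherits(fit, "quench_fit")) fit$kq else fit
  trend <- NA
  if (!is.null(fits_by_t)) {
    tab <- if (is.data.frame(fits_by_t)) {
      fits_by_t
    } else {
      tibble::tibble(
        temperature_k = purrr::map_dbl(fits_by_t, "temperature_k"),
        ksv = purrr::map_dbl(fits_by_t, "ksv")
      )
    }
    tab <- dplyr::arrange(tab, .data$temperature_k)
    if (nrow(tab) >= 2) trend <- all(diff(tab$ksv) < 0)
  }
  tibble::tibble(
    kq = kq,
    mechanism = dplyr::case_when(
      kq > dynamic_limit ~ "static",
      kq < dynamic_limit ~ "dynamic",
      TRUE ~ "indeterminate"
    ),
    ksv_decreasing_with_t = trend
  )
}

#' Competitive displacement of a bound fluorescent probe
#'
#' Percent exchange per titration point, `%Ex = (F0 - F)/F0 * 100`, for a
#' competitive displacement assay (e.g. ethidium bromide released from DNA
#' by a competing ligand). Scale-invariant: multiplying all intensities by a
#' constant changes nothing.
#'
#' @param data A data frame of readouts or a [titration_series()].
#' @param conc,f Column names for ligand concentration and fluorescence.
#' @param f0 Fluorescence of the probe-macromolecule complex alone.
#' @param ... Passed to methods (`policy` for series input).
#' @return A tibble with columns `titrant_conc`, `percent_ex`, carrying the
#'   attribute `max_percent` (the maximum exchange over the series).
#' @examples
#' displacement(data.frame(titrant_conc = 1e-6, value = 0.7094 * 500),
#'              f0 = 500)  # 29.06%
#' @export
displacement <- function(data, ...) UseMethod("displacement")

#' @rdname displacement
#' @export
displacement.titration_series <- function(data, ..., policy = readout_policy()) {
  r <- readout_at(data, policy)
  displacement(r, conc = "titrant_conc", f = "value", f0 = attr(r, "base_value"))
}

#' @rdname displacement
#' @export
displacement.data.frame <- function(data, conc = "titrant_conc", f = "value",
                                    f0, ...) {
  if (f0 <= 0) stop_domain("`f0` must be > 0.")
  out <- tibble::tibble(
    titrant_conc = data[[conc]],
    percent_ex = (f0 - data[[f]]) / f0 * 100
  )
  attr(out, "max_percent") <- max(out$percent_ex)
  class(out) <- c("displacement_result", class(out))
  out
}

#' @export
print.displacement_result <- function(x, ...) {
  cat(sprintf("<displacement: max %%Ex = %.2f over %d points>\n",
              attr(x, "max_percent"), nrow(x)))
  NextMethod()
}

#' Iodide protection of a fluorophore by a macromolecule
#'
#' Compares Stern-Volmer constants of a ligand quenched by iodide with and
#' without the macromolecule present. An intercalated fluorophore is
#' shielded from the anionic quencher, so its Ksv drops sharply when DNA is
#' added; a reduction below `threshold` (default 45%) indicates groove or
#' mixed binding.
#'
#' @param fit_absent,fit_present `quench_fit`s (or bare Ksv numerics) for the
#'   ligand + KI series without and with the macromolecule.
#' @param threshold Percent reduction at or above which the protection is
#'   called intercalation-consistent.
#' @return A tibble with `ksv_absent`, `ksv_present`, `reduction_percent`
#'   and `classification` (`"groove_or_mixed"` / `"intercalation_protective"`).
#' @examples
#' ki_protection(33.77e3, 32.24e3)  # 4.5% reduction
#' @export
ki_protection <- function(fit_absent, fit_present, threshold = 45) {
  ka <- if (inherits(fit_absent, "quench_fit")) fit_absent$ksv else fit_absent
  kp <- if (inherits(fit_present, "quench_fit")) fit_present$ksv else fit_present
  if (any(ka <= 0)) stop_domain("Ksv without the macromolecule must be > 0.")
  red <- (ka - kp) / ka * 100
  tibble::tibble(
    ksv_absent = ka, ksv_present = kp,
    reduction_percent = red,
    classification = ifelse(red >= threshold,
                            "intercalation_protective", "groove_or_mixed")
  )
}

#' Ionic-strength trend of a ligand-DNA complex
#'
#' OLS slope of the relative fluorescence `F/F0` against salt concentration.
#' A significantly positive slope (|slope| > 2 standard errors) means salt
#' releases the ligand, i.e. an electrostatic binding component; a
#' significantly negative slope rules it out; otherwise flat.
#'
#' @param data A data frame of readouts or a [titration_series()] with salt
#'   as the titrant.
#' @param conc,f Column names for salt concentration (mol/L) and
#'   fluorescence.
#' @param f0 Fluorescence at zero added salt.
#' @param ... Passed to methods (`policy` for series input).
#' @return A tibble with `slope` (per M), `stderr_slope` and
#'   `classification` (`"electrostatic_component"`, `"no_electrostatic"`,
#'   `"flat"`).
#' @export
ionic_strength_trend <- function(data, ...) UseMethod("ionic_strength_trend")

#' @rdname ionic_strength_trend
#' @export
ionic_strength_trend.titration_series <- function(data, ..., policy = readout_policy()) {
  r <- readout_at(data, policy)
  ionic_strength_trend(r, conc = "titrant_conc", f = "value",
                       f0 = attr(r, "base_value"))
}

#' @rdname ionic_strength_trend
#' @export
ionic_strength_trend.data.frame <- function(data, conc = "titrant_conc",
                                            f = "value", f0, ...) {
  if (f0 <= 0) stop_domain("`f0` must be > 0.")
  cc <- data[[conc]]
  rel <- data[[f]] / f0
  if (length(cc) < 3) stop_validation("Ionic-strength trend needs at least 3 points.")
  fit <- lm(rel ~ cc)
  slope <- coef(fit)[[2]]
  se <- summary(fit)$coefficients[2, 2]
  cls <- if (is.na(se) || abs(slope) <= 2 * se) {
    "flat"
  } else if (slope > 0) {
    "electrostatic_component"
  } else {
    "no_electrostatic"
  }
  tibble::tibble(slope = slope, stderr_slope = se, classification = cls)
}
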