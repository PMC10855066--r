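#' Double-logarithm binding fit
#'
#' OLS of `log10((F0 - F)/F)` on `log10([Q])`:
#' `log10((F0 - F)/F) = log10(Kb) + n log10([Q])`. The intercept is
#' `log10(Kb)` and the slope the number of binding sites `n`. `Kb = 10^logKb`
#' holds exactly on the returned object. Inputs are expected to be
#' inner-filter-corrected.
#'
#' @param data A data frame of readouts or a [titration_series()].
#' @param conc,f Column names for quencher concentration (mol/L) and
#'   fluorescence.
#' @param f0 Unquenched fluorescence; every `f` must lie strictly between 0
#'   and `f0` (otherwise the logarithm is undefined and the offending
#'   concentration is named).
#' @param ... Passed to methods (`policy` for series input).
#' @return A `binding_fit`: fields `log_kb`, `kb`, `n`, `stderr_log_kb`,
#'   `stderr_n`, `r2`, `temperature_k` (if known). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' s <- gen_quench(ground_truth(k_true = 1e5, n_true = 1, noise_sd = 0),
#'                 model = "log_linear")
#' double_log_fit(s)  # logKb = 5, n = 1
#' @export
double_log_fit <- function(data, ...) UseMethod("double_log_fit")

#' @rdname double_log_fit
#' @export
double_log_fit.titration_series <- function(data, ..., policy = readout_policy()) {
  r <- readout_at(data, policy)
  out <- double_log_fit(r, conc = "titrant_conc", f = "value",
                        f0 = attr(r, "base_value"))
  out$temperature_k <- data$temperature_k
  out
}

#' @rdname double_log_fit
#' @export
double_log_fit.data.frame <- function(data, conc = "titrant_conc", f = "value",
                                      f0, ...) {
  q <- data[[conc]]
  ff <- data[[f]]
  if (length(q) < 3) stop_validation("The double-logarithm fit needs at least 3 points.")
  if (f0 <= 0) stop_domain("`f0` must be > 0.")
  bad <- which(ff >= f0 | ff <= 0)
  if (length(bad)) {
    stop_domain(sprintf(
      "F must lie strictly between 0 and F0; violated at concentration %.6g (F = %.6g, F0 = %.6g).",
      q[bad[1]], ff[bad[1]], f0
    ))
  }
  y <- log10((f0 - ff) / ff)
  x <- log10(q)
  fit <- lm(y ~ x)
  b <- coef(fit)
  se <- summary(fit)$coefficients[, 2]
  structure(list(
    log_kb = b[[1]], kb = 10^b[[1]], n = b[[2]],
    stderr_log_kb = se[[1]], stderr_n = se[[2]],
    r2 = summary(fit)$r.squared,
    f0 = f0, n_points = length(q), temperature_k = NA_real_,
    data = tibble::tibble(conc = q, f = ff, x = x, y = y),
    lm = fit
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<double-log binding fit: logKb = %.3f (se %.3f), Kb = %.4g 1/M, n = %.3f (se %.3f), r2 = %.4f>\n",
              x$log_kb, x$stderr_log_kb, x$kb, x$n, x$stderr_n, x$r2))
  invisible(x)
}

#' Van't Hoff analysis of binding constants over temperature
#'
#' OLS of `ln Kb` on `1/T`: `ln Kb = -dH/(R T) + dS/R` with
#' `R = 8.314` J/(mol K); the natural-log form is the dimensionally
#' consistent one for R-scaled slope and intercept. `dH = -R * slope` and
#' `dS = R * intercept`; `dG(T) = dH - T dS` is evaluated at every input
#' temperature.
#'
#' @param data A data frame with temperature and binding-constant columns
#'   (e.g. the output of [gen_vant_hoff()]), or a list of `binding_fit`s
#'   carrying their temperatures.
#' @param temperature_k,kb Column names for kelvin temperature and binding
#'   constant (1/M).
#' @param ... Passed to methods.
#' @return A `thermo_fit`: fields `dh` (J/mol), `ds` (J/(mol K)), `dg_by_t`
#'   (tibble of `temperature_k`, `dg`), `r2`, and the input table. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' vant_hoff(gen_vant_hoff(ground_truth(dh_true = -1e5, ds_true = -250,
#'                                      noise_sd = 0)))
#' @export
vant_hoff <- function(data, ...) UseMethod("vant_hoff")

#' @rdname vant_hoff
#' @export
vant_hoff.list <- function(data, ...) {
  tab <- tibble::tibble(
    temperature_k = purrr::map_dbl(data, "temperature_k"),
    kb = purrr::map_dbl(data, "kb")
  )
  vant_hoff(tab, ...)
}

#' @rdname vant_hoff
#' @export
vant_hoff.data.frame <- function(data, temperature_k = "temperature_k",
                                 kb = "kb", ...) {
  tt <- data[[temperature_k]]
  kk <- data[[kb]]
  if (length(unique(tt)) < 2) {
    stop_validation("Van't Hoff analysis needs at least 2 distinct temperatures.")
  }
  if (any(tt <= 0)) stop_domain("Temperatures must be positive kelvin.")
  if (any(kk <= 0)) stop_domain("All binding constants must be > 0.")
  y <- log(kk)
  x <- 1 / tt
  fit <- lm(y ~ x)
  b <- coef(fit)
  dh <- -R_GAS * b[[2]]
  ds <- R_GAS * b[[1]]
  structure(list(
    dh = dh, ds = ds,
    dg_by_t = tibble::tibble(temperature_k = sort(unique(tt)),
                             dg = dh - sort(unique(tt)) * ds),
    r2 = summary(fit)$r.squared,
    data = tibble::tibble(temperature_k = tt, kb = kk),
    lm = fit
  ), class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat(sprintf("<van't Hoff fit: dH = %.4g kJ/mol, dS = %.4g J/(mol K), r2 = %.4f>\n",
              x$dh / 1e3, x$ds, x$r2))
  print(dplyr::mutate(x$dg_by_t, dg_kj = .data$dg / 1e3))
  invisible(x)
}

#' Report the Gibbs energy of binding at the reference temperature
#'
#' Evaluates both defining routes at the lowest measured temperature and
#' reports the one selected by `policy`:
#' * `"from_enthalpy"` (default): `dG = dH - T dS`;
#' * `"from_k"`: `dG = -R T ln(Kb)` using the binding constant measured at
#'   that temperature.
#'
#' Both numbers are always recorded so their (usually small) disagreement is
#' visible.
#'
#' @param th A `thermo_fit` from [vant_hoff()].
#' @param policy Which route supplies the reported `dg`.
#' @return A one-row tibble: `temperature_k`, `dg_from_enthalpy`,
#'   `dg_from_k` (J/mol; `NA` if no constant was measured at the reference
#'   temperature), `policy`, `dg`.
#' @export
gibbs_report <- function(th, policy = c("from_enthalpy", "from_k")) {
  policy <- match.arg(policy)
  stopifnot(inherits(th, "thermo_fit"))
  t_ref <- min(th$data$temperature_k)
  dg_h <- th$dh - t_ref * th$ds
  kb_ref <- th$data$kb[th$data$temperature_k == t_ref][1]
  dg_k <- if (is.na(kb_ref)) NA_real_ else gibbs_from_k(kb_ref, t_ref)
  tibble::tibble(
    temperature_k = t_ref,
    dg_from_enthalpy = dg_h,
    dg_from_k = dg_k,
    policy = policy,
    dg = if (policy == "from_enthalpy") dg_h else dg_k
  )
}

#' Dominant interaction forces from thermodynamic signatures
#'
#' The classical solution-thermodynamics rules for protein-ligand binding:
#' negative enthalpy and entropy indicate hydrogen bonding and van der Waals
#' contacts; positive enthalpy and entropy indicate hydrophobic interaction;
#' near-zero enthalpy (|dH| < `dh_tol`) with positive entropy indicates
#' electrostatic interaction; anything else is reported as mixed.
#'
#' @param dh Binding enthalpy, J/mol. Vectorized.
#' @param ds Binding entropy, J/(mol K).
#' @param dh_tol Enthalpy magnitude below which dH counts as "about zero"
#'   (default 4000 J/mol).
#' @return Character vector: `"hbond_vdw"`, `"hydrophobic"`,
#'   `"electrostatic"` or `"mixed"`.
#' @examples
#' interaction_forces(-155.65e3, -432.83)  # hydrogen bonds + van der Waals
#' @export
interaction_forces <- function(dh, ds, dh_tol = 4e3) {
  dplyr::case_when(
    abs(dh) < dh_tol & ds > 0 ~ "electrostatic",
    dh < 0 & ds < 0 ~ "hbond_vdw",
    dh > 0 & ds > 0 ~ "hydrophobic",
    TRUE ~ "mixed"
  )
}
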