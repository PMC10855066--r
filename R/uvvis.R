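#' Percent chromism of an absorbance change
#'
#' `percent = (A0 - A)/A0 * 100`. Under this sign convention a hyperchromic
#' effect (absorbance rising on complexation, `A > A0`) gives a negative
#' signed percent; results are therefore reported as a magnitude plus a
#' direction flag, which is how chromism tables are conventionally printed.
#'
#' @param a0 Absorbance without the macromolecule (> 0).
#' @param a Absorbance at the final titration point. Vectorized.
#' @return A tibble with columns `percent` (signed), `magnitude` (`|percent|`)
#'   and `direction` (`"hypochromic"` if the signal fell, `"hyperchromic"` if
#'   it rose, `"none"` if unchanged).
#' @examples
#' chromism(1.0, 1.1161)  # 11.61% hyperchromic
#' chromism(1.0, 0.9)     # 10% hypochromic
#' @export
chromism <- function(a0, a) {
  if (any(a0 <= 0)) stop_domain("`a0` must be > 0.")
  percent <- (a0 - a) / a0 * 100
  tibble::tibble(
    percent = percent,
    magnitude = abs(percent),
    direction = dplyr::case_when(
      percent > 0 ~ "hypochromic",
      percent < 0 ~ "hyperchromic",
      TRUE ~ "none"
    )
  )
}

#' Benesi-Hildebrand fit of an apparent association constant
#'
#' Ordinary least squares of the double-reciprocal linearization of the 1:1
#' complexation isotherm:
#' `1/(A_obs - A0) = 1/(Ac - A0) + 1/(Kapp (Ac - A0)) * 1/c`,
#' so `Kapp = intercept / slope` and `Ac = A0 + 1/intercept`. The standard
#' error of `Kapp` follows by first-order propagation from the OLS
#' coefficient covariance.
#'
#' @param data A data frame of titration readouts, or a
#'   [titration_series()] (reduced with [readout_at()], `A0` taken from the
#'   base spectrum).
#' @param conc,a_obs Column names (tidy-eval) holding the titrant
#'   concentration (mol/L) and observed absorbance. Defaults match
#'   [readout_at()] output.
#' @param a0 Reference absorbance at zero titrant.
#' @param ... Passed to methods ([readout_policy()] via `policy` for series
#'   input).
#' @return A `bh_fit` object: fields `kapp`, `ac`, `slope`, `intercept`,
#'   `r2`, `stderr_kapp`, `n_points`, plus the underlying `lm`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' benesi_hildebrand(gen_uvvis(ground_truth(k_true = 5e3, noise_sd = 0)))
#' @export
benesi_hildebrand <- function(data, ...) UseMethod("benesi_hildebrand")

#' @rdname benesi_hildebrand
#' @export
benesi_hildebrand.titration_series <- function(data, ..., policy = readout_policy()) {
  r <- readout_at(data, policy)
  benesi_hildebrand(r, conc = "titrant_conc", a_obs = "value",
                    a0 = attr(r, "base_value"))
}

#' @rdname benesi_hildebrand
#' @export
benesi_hildebrand.data.frame <- function(data, conc = "titrant_conc",
                                         a_obs = "value", a0, ...) {
  cc <- data[[conc]]
  aa <- data[[a_obs]]
  if (length(cc) < 3) stop_validation("Benesi-Hildebrand needs at least 3 titration points.")
  diff_a <- aa - a0
  if (any(diff_a == 0)) {
    stop_singular(sprintf(
      "A_obs equals A0 at concentration %.6g; the reciprocal transform is singular there.",
      cc[which(diff_a == 0)[1]]
    ))
  }
  if (length(unique(sign(diff_a))) > 1) {
    stop_validation("Mixed signs of (A_obs - A0): the titration changes direction; not a 1:1 isotherm.")
  }
  y <- 1 / diff_a
  x <- 1 / cc
  if (length(unique(y)) == 1) {
    stop_singular("All reciprocal absorbance changes are equal: zero slope, Kapp unidentifiable.")
  }
  fit <- lm(y ~ x)
  b <- coef(fit)
  if (!is.finite(b[[2]]) || b[[2]] == 0 || !is.finite(b[[1]]) || b[[1]] == 0) {
    stop_singular("Degenerate Benesi-Hildebrand fit: zero slope or intercept (Kapp unidentifiable).")
  }
  V <- vcov(fit)
  kapp <- b[[1]] / b[[2]]
  # delta method for Kapp = b0/b1
  g <- c(1 / b[[2]], -b[[1]] / b[[2]]^2)
  stderr_kapp <- sqrt(drop(t(g) %*% V %*% g))
  structure(list(
    kapp = kapp,
    ac = a0 + 1 / b[[1]],
    slope = b[[2]], intercept = b[[1]],
    r2 = summary(fit)$r.squared,
    stderr_kapp = stderr_kapp,
    a0 = a0, n_points = length(cc),
    data = tibble::tibble(conc = cc, a_obs = aa, x = x, y = y),
    lm = fit
  ), class = "bh_fit")
}

#' @export
print.bh_fit <- function(x, ...) {
  cat(sprintf("<Benesi-Hildebrand fit: Kapp = %.4g 1/M (se %.2g), Ac = %.4g, r2 = %.4f, %d points>\n",
              x$kapp, x$stderr_kapp, x$ac, x$r2, x$n_points))
  invisible(x)
}

#' Gibbs energy from an equilibrium constant
#'
#' `dG = -R T ln(K)` with `R = 8.314` J/(mol K). Vectorized over `k` and
#' `temperature_k`.
#'
#' @param k Equilibrium constant (1/M), > 0.
#' @param temperature_k Temperature in kelvin, > 0.
#' @return Gibbs energy change in J/mol.
#' @examples
#' gibbs_from_k(7.02e3, 298)  # about -2.19e4 J/mol
#' @export
gibbs_from_k <- function(k, temperature_k) {
  if (any(k <= 0)) stop_domain("`k` must be > 0.")
  if (any(temperature_k <= 0)) stop_domain("`temperature_k` must be > 0.")
  -R_GAS * temperature_k * log(k)
}

#' Classify the DNA binding mode from an apparent association constant
#'
#' Apparent association constants of order 1e2-1e3 1/M are too low for
#' intercalation, whose reference point is the classical intercalator
#' ethidium bromide with `Kapp = 1.23e5` 1/M; constants at or above 1e5 are
#' intercalation-consistent. Values between the two bounds are labelled
#' groove-or-mixed with an indeterminacy flag.
#'
#' @param fit A `bh_fit` or a numeric `Kapp` (1/M); vectorized for numerics.
#' @param lower Below this bound the verdict is groove-or-mixed (default 1e4).
#' @param upper At or above this bound the verdict is intercalation-likely
#'   (default 1e5).
#' @return A tibble with columns `kapp`, `mode`
#'   (`"groove_or_mixed"`/`"intercalation_likely"`) and `indeterminate`.
#' @export
classify_uvvis_mode <- function(fit, lower = 1e4, upper = 1e5) {
  kapp <- if (inherits(fit, "bh_fit")) fit$kapp else fit
  if (any(kapp <= 0)) stop_domain("`Kapp` must be > 0.")
  tibble::tibble(
    kapp = kapp,
    mode = ifelse(kapp >= upper, "intercalation_likely", "groove_or_mixed"),
    indeterminate = kapp >= lower & kapp < upper
  )
}
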