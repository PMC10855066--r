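# ggplot2 autoplot methods: diagnostic figures for each result type

#' Plot a titration series
#'
#' Overlays all spectra of the series, colored by titrant concentration; the
#' base spectrum is the zero-concentration trace.
#'
#' @param object A [titration_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.titration_series <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$intensity,
                                   group = .data$titrant_conc,
                                   colour = .data$titrant_conc)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = spectrum_mode(object$base),
                  colour = "titrant (M)",
                  title = sprintf("%s titration, T = %g K",
                                  object$assay, object$temperature_k)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bh_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "1/[titrant] (1/M)", y = "1/(A - A0)",
                  title = sprintf("Benesi-Hildebrand: Kapp = %.3g 1/M, r2 = %.4f",
                                  object$kapp, object$r2)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.quench_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$conc, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$ksv,
                         colour = "steelblue") +
    ggplot2::labs(x = "[Q] (M)", y = "F0/F",
                  title = sprintf("Stern-Volmer: Ksv = %.3g 1/M, kq = %.3g 1/(M s)",
                                  object$ksv, object$kq)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.binding_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$log_kb, slope = object$n,
                         colour = "steelblue") +
    ggplot2::labs(x = "log10 [Q]", y = "log10 (F0 - F)/F",
                  title = sprintf("Double-log fit: logKb = %.3f, n = %.3f",
                                  object$log_kb, object$n)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.thermo_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, x = 1 / .data$temperature_k,
                      y = log(.data$kb))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "1/T (1/K)", y = "ln Kb",
                  title = sprintf("van't Hoff: dH = %.3g kJ/mol, dS = %.3g J/(mol K)",
                                  object$dh / 1e3, object$ds)) +
    ggplot2::theme_minimal()
}
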