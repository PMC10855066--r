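#' Construct a single spectrum
#'
#' A spectrum is a wavelength-indexed intensity trace: absorbance
#' (dimensionless), fluorescence emission (arbitrary units) or a CD signal.
#' Wavelengths must be strictly increasing; absorbance must be non-negative
#' (spectra are assumed baseline-corrected upstream).
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing,
#'   length at least 2.
#' @param intensity Numeric vector of the same length.
#' @param mode One of `"absorbance"`, `"fluorescence"`, `"cd"`.
#'
#' @return A tibble of class `spectrum` with columns `wavelength` and
#'   `intensity` and a `mode` attribute.
#' @examples
#' sp <- spectrum(seq(300, 400, 10), dnorm(seq(300, 400, 10), 340, 25))
#' sp
#' @export
spectrum <- function(wavelength, intensity,
                     mode = c("fluorescence", "absorbance", "cd")) {
  mode <- match.arg(mode)
  if (!is.numeric(wavelength) || !is.numeric(intensity)) {
    stop_validation("`wavelength` and `intensity` must be numeric.")
  }
  if (length(wavelength) < 2) {
    stop_validation("A spectrum needs at least 2 wavelength channels.")
  }
  if (length(wavelength) != length(intensity)) {
    stop_validation(sprintf(
      "`wavelength` (%d) and `intensity` (%d) lengths differ.",
      length(wavelength), length(intensity)
    ))
  }
  if (anyNA(wavelength) || anyNA(intensity)) {
    stop_validation("Spectra must not contain missing values.")
  }
  if (any(diff(wavelength) <= 0)) {
    stop_validation("`wavelength` must be strictly increasing.")
  }
  if (mode == "absorbance" && any(intensity < 0)) {
    stop_domain("Absorbance intensities must be >= 0 (baseline-corrected input expected).")
  }
  out <- tibble::tibble(wavelength = as.numeric(wavelength),
                        intensity = as.numeric(intensity))
  attr(out, "mode") <- mode
  class(out) <- c("spectrum", class(out))
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d channels, %.1f-%.1f nm>\n",
              spectrum_mode(x), nrow(x), min(x$wavelength), max(x$wavelength)))
  NextMethod()
}

#' Mode of a spectrum
#' @param x A [spectrum()].
#' @return `"absorbance"`, `"fluorescence"` or `"cd"`.
#' @export
spectrum_mode <- function(x) attr(x, "mode")

is_spectrum <- function(x) inherits(x, "spectrum")
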