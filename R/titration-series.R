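#' Construct a titration series
#'
#' An ordered collection of spectra recorded while a titrant (DNA, quencher,
#' salt or ligand) is added to a fixed-concentration species. The base
#' spectrum is the zero-titrant reference that supplies `A0` or `F0`. All
#' spectra must share one wavelength grid with the base, exactly: resampling
#' mismatched grids upstream is a data error, never silently repaired here.
#'
#' @param base A [spectrum()]: the zero-titrant reference.
#' @param points A data frame with a numeric `titrant_conc` column (mol/L,
#'   strictly increasing, all positive) and a `spectrum` list-column of
#'   [spectrum()] objects.
#' @param temperature_k Temperature in kelvin (> 0).
#' @param assay Assay role, one of `"uvvis_dna"`, `"eb_displacement"`,
#'   `"ki_quench"`, `"ionic_strength"`, `"protein_quench"`.
#' @param fixed_species_conc Concentration (mol/L) of the fixed species
#'   (ligand or protein); `NA` if unknown.
#' @param path_length_cm Optical path length in cm (default 1).
#' @param meta Named list of free-form metadata (e.g. the generating model of
#'   a synthetic series).
#'
#' @return An object of class `titration_series`.
#' @seealso [read_series()], [readout_at()], [as_tibble.titration_series()]
#' @export
titration_series <- function(base, points,
                             temperature_k = 297,
                             assay = c("uvvis_dna", "eb_displacement",
                                       "ki_quench", "ionic_strength",
                                       "protein_quench"),
                             fixed_species_conc = NA_real_,
                             path_length_cm = 1,
                             meta = list()) {
  assay <- match.arg(assay)
  if (!is_spectrum(base)) stop_validation("`base` must be a spectrum.")
  points <- tibble::as_tibble(points)
  if (!all(c("titrant_conc", "spectrum") %in% names(points))) {
    stop_validation("`points` needs columns `titrant_conc` and `spectrum`.")
  }
  conc <- points$titrant_conc
  if (anyNA(conc) || any(conc <= 0)) {
    stop_validation("All `titrant_conc` values must be positive.")
  }
  if (any(diff(conc) <= 0)) {
    stop_validation("`titrant_conc` must be strictly increasing (duplicates are not allowed).")
  }
  if (!is.numeric(temperature_k) || length(temperature_k) != 1 || temperature_k <= 0) {
    stop_validation("`temperature_k` must be a single positive number.")
  }
  grid <- base$wavelength
  for (i in seq_len(nrow(points))) {
    sp <- points$spectrum[[i]]
    if (!is_spectrum(sp)) stop_validation("Every element of `points$spectrum` must be a spectrum.")
    if (!isTRUE(all.equal(sp$wavelength, grid, tolerance = 0))) {
      stop_grid(sprintf(
        "Wavelength grid of point %d (conc %.4g) does not match the base grid; resample upstream before construction.",
        i, conc[i]
      ))
    }
  }
  structure(
    list(base = base, points = points,
         temperature_k = temperature_k, assay = assay,
         fixed_species_conc = fixed_species_conc,
         path_length_cm = path_length_cm, meta = meta),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series: %s, %d points + base, %s, T = %g K>\n",
    x$assay, nrow(x$points), spectrum_mode(x$base), x$temperature_k
  ))
  cat(sprintf("  titrant: %.4g to %.4g mol/L; grid %.1f-%.1f nm (%d channels)\n",
              min(x$points$titrant_conc), max(x$points$titrant_conc),
              min(x$base$wavelength), max(x$base$wavelength), nrow(x$base)))
  invisible(x)
}

#' Wavelength grid of a titration series
#' @param series A [titration_series()].
#' @return Numeric vector of wavelengths (nm).
#' @export
series_grid <- function(series) series$base$wavelength

#' Flatten a titration series to a long tibble
#'
#' The base spectrum appears with `titrant_conc = 0`.
#'
#' @param x A [titration_series()].
#' @param ... Unused.
#' @return A tibble with columns `titrant_conc`, `wavelength`, `intensity`.
#' @exportS3Method tibble::as_tibble
as_tibble.titration_series <- function(x, ...) {
  rows <- c(
    list(tibble::tibble(titrant_conc = 0,
                        wavelength = x$base$wavelength,
                        intensity = x$base$intensity)),
    purrr::map2(x$points$titrant_conc, x$points$spectrum, function(conc, sp) {
      tibble::tibble(titrant_conc = conc,
                     wavelength = sp$wavelength,
                     intensity = sp$intensity)
    })
  )
  dplyr::bind_rows(rows)
}

is_titration_series <- function(x) inherits(x, "titration_series")
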