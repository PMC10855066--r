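#' Read a titration series from CSV
#'
#' Two CSV dialects are supported (UTF-8, header row, `.` decimal separator):
#'
#' * **long**: columns `titrant_conc`, `wavelength`, `intensity` (an optional
#'   `series_id` column is ignored). The base spectrum is the block with
#'   `titrant_conc == 0`.
#' * **wide**: a `wavelength` column plus one column per concentration, the
#'   column name being the molar concentration (`"0"` for the base).
#'
#' Row order in the file never affects the result: rows are sorted by
#' concentration and wavelength before the series is assembled. Every
#' concentration block must share the base wavelength grid exactly.
#'
#' @param path Path to a CSV file.
#' @param layout `"long"` or `"wide"`.
#' @param mode Spectrum mode, see [spectrum()].
#' @inheritParams titration_series
#' @return A validated [titration_series()].
#' @examples
#' s <- gen_quench(ground_truth(k_true = 1e5, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_series(s, f, layout = "long")
#' s2 <- read_series(f, layout = "long", mode = "fluorescence",
#'                   assay = "protein_quench")
#' all.equal(readout_at(s2)$value, readout_at(s)$value)
#' @export
read_series <- function(path, layout = c("long", "wide"),
                        mode = c("fluorescence", "absorbance", "cd"),
                        temperature_k = 297,
                        assay = c("uvvis_dna", "eb_displacement", "ki_quench",
                                  "ionic_strength", "protein_quench"),
                        fixed_species_conc = NA_real_,
                        path_length_cm = 1) {
  layout <- match.arg(layout)
  mode <- match.arg(mode)
  assay <- match.arg(assay)
  if (!file.exists(path)) stop_validation(sprintf("Input file does not exist: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  tab <- if (layout == "long") parse_long(raw) else parse_wide(raw)
  assemble_series(tab, mode = mode, temperature_k = temperature_k,
                  assay = assay, fixed_species_conc = fixed_species_conc,
                  path_length_cm = path_length_cm)
}

# parse a character column, reporting the first offending CSV row (1-based
# data rows, header excluded)
parse_numeric_col <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "")
  if (anyNA(out) || length(bad)) {
    row <- if (length(bad)) bad[1] else which(is.na(out))[1]
    stop_parse(sprintf("Non-numeric value in column `%s` at data row %d: \"%s\"",
                       name, row, x[row]))
  }
  out
}

parse_long <- function(raw) {
  need <- c("titrant_conc", "wavelength", "intensity")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_parse(sprintf("Long layout requires columns %s; missing: %s",
                       paste(need, collapse = ", "), paste(miss, collapse = ", ")))
  }
  tibble::tibble(
    titrant_conc = parse_numeric_col(raw$titrant_conc, "titrant_conc"),
    wavelength = parse_numeric_col(raw$wavelength, "wavelength"),
    intensity = parse_numeric_col(raw$intensity, "intensity")
  )
}

parse_wide <- function(raw) {
  if (!"wavelength" %in% names(raw)) {
    stop_parse("Wide layout requires a `wavelength` column.")
  }
  conc_names <- setdiff(names(raw), "wavelength")
  concs <- suppressWarnings(as.numeric(conc_names))
  if (anyNA(concs)) {
    stop_parse(sprintf("Wide layout column names must be molar concentrations; offending: %s",
                       paste(conc_names[is.na(concs)], collapse = ", ")))
  }
  wl <- parse_numeric_col(raw$wavelength, "wavelength")
  purrr::map2_dfr(conc_names, concs, function(nm, cc) {
    tibble::tibble(titrant_conc = cc, wavelength = wl,
                   intensity = parse_numeric_col(raw[[nm]], nm))
  })
}

assemble_series <- function(tab, mode, temperature_k, assay,
                            fixed_species_conc, path_length_cm) {
  tab <- dplyr::arrange(tab, .data$titrant_conc, .data$wavelength)
  concs <- sort(unique(tab$titrant_conc))
  if (any(concs < 0)) stop_validation("Concentrations must be >= 0 (0 marks the base spectrum).")
  if (!0 %in% concs) stop_validation("No base spectrum found (rows with titrant_conc == 0).")
  if (length(concs) < 2) stop_validation("A series needs a base spectrum and at least one titration point.")
  blocks <- split(tab, tab$titrant_conc)
  grid <- blocks[[as.character(0)]]$wavelength
  if (anyDuplicated(grid)) {
    stop_grid("Duplicated wavelengths within one concentration block.")
  }
  specs <- purrr::map(blocks, function(b) {
    if (!identical(length(b$wavelength), length(grid)) ||
        !isTRUE(all.equal(b$wavelength, grid, tolerance = 0))) {
      stop_grid(sprintf(
        "Wavelength grid at titrant_conc %.6g differs from the base grid (%d vs %d channels).",
        b$titrant_conc[1], length(b$wavelength), length(grid)
      ))
    }
    spectrum(b$wavelength, b$intensity, mode = mode)
  })
  pos <- setdiff(concs, 0)
  titration_series(
    base = specs[[as.character(0)]],
    points = tibble::tibble(
      titrant_conc = pos,
      spectrum = purrr::map(as.character(pos), function(k) specs[[k]])
    ),
    temperature_k = temperature_k, assay = assay,
    fixed_species_conc = fixed_species_conc, path_length_cm = path_length_cm
  )
}

#' Write a titration series to CSV
#'
#' Inverse of [read_series()]: `read_series(write_series(s, f, layout), layout)`
#' is value-identical to `s` on the same layout.
#'
#' @param series A [titration_series()].
#' @param path Output CSV path.
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  long <- as_tibble(series)
  if (layout == "long") {
    readr::write_csv(long, path, progress = FALSE)
  } else {
    wide <- tidyr::pivot_wider(long, names_from = "titrant_conc",
                               values_from = "intensity")
    readr::write_csv(wide, path, progress = FALSE)
  }
  invisible(path)
}

#' Export / import a titration series as JSON
#'
#' Full-precision JSON serialization, used for fixture sidecars and reports.
#'
#' @param series A [titration_series()].
#' @param path JSON file path.
#' @return `write_series_json()` returns `path` invisibly; `read_series_json()`
#'   returns a [titration_series()].
#' @export
write_series_json <- function(series, path) {
  payload <- list(
    mode = spectrum_mode(series$base),
    temperature_k = series$temperature_k,
    assay = series$assay,
    fixed_species_conc = series$fixed_species_conc,
    path_length_cm = series$path_length_cm,
    meta = series$meta,
    wavelength = series$base$wavelength,
    base_intensity = series$base$intensity,
    points = purrr::map2(
      series$points$titrant_conc, series$points$spectrum,
      function(conc, sp) list(titrant_conc = conc, intensity = sp$intensity)
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series_json
#' @export
read_series_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  wl <- as.numeric(p$wavelength)
  mode <- p$mode
  titration_series(
    base = spectrum(wl, as.numeric(p$base_intensity), mode = mode),
    points = tibble::tibble(
      titrant_conc = purrr::map_dbl(p$points, "titrant_conc"),
      spectrum = purrr::map(p$points, function(pt) {
        spectrum(wl, as.numeric(pt$intensity), mode = mode)
      })
    ),
    temperature_k = p$temperature_k, assay = p$assay,
    fixed_species_conc = if (is.null(p$fixed_species_conc)) NA_real_ else p$fixed_species_conc,
    path_length_cm = p$path_length_cm,
    meta = if (is.null(p$meta)) list() else p$meta
  )
}
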