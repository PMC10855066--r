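#' Define a readout policy
#'
#' A readout policy picks the single wavelength channel (or narrow band) at
#' which a titration series is reduced to one value per spectrum — e.g. the
#' 603 nm emission channel of an ethidium bromide / DNA displacement assay.
#'
#' With `source = "peak_max"` the channel is the intensity maximum of the
#' *base* spectrum inside `window`, and is then held fixed for every
#' titration point, so quenching or chromism can never shift the readout
#' channel mid-series. Ties between equal maxima break to the smallest
#' wavelength. With `source = "fixed_wavelength"` the stated channel must be
#' present in the grid exactly.
#'
#' @param source `"peak_max"` or `"fixed_wavelength"`.
#' @param wavelength_nm Channel for `"fixed_wavelength"`.
#' @param window Length-2 numeric `c(lo, hi)` search window (nm) for
#'   `"peak_max"`; default is the whole grid.
#' @param band_nm Optional full band width (nm) over which intensities are
#'   averaged around the chosen channel; `0` (default) reads the single
#'   channel.
#' @return A `readout_policy` object.
#' @export
readout_policy <- function(source = c("peak_max", "fixed_wavelength"),
                           wavelength_nm = NULL, window = NULL, band_nm = 0) {
  source <- match.arg(source)
  if (source == "fixed_wavelength" && is.null(wavelength_nm)) {
    stop_validation("`fixed_wavelength` policy requires `wavelength_nm`.")
  }
  if (!is.null(window)) {
    if (length(window) != 2 || !is.numeric(window) || window[1] > window[2]) {
      stop_validation("`window` must be numeric c(lo, hi) with lo <= hi.")
    }
  }
  if (!is.numeric(band_nm) || band_nm < 0) stop_validation("`band_nm` must be >= 0.")
  structure(list(source = source, wavelength_nm = wavelength_nm,
                 window = window, band_nm = band_nm),
            class = "readout_policy")
}

#' Reduce a titration series to one value per titration point
#'
#' @param series A [titration_series()].
#' @param policy A [readout_policy()]; the default reads the base-spectrum
#'   peak over the whole grid.
#' @return A tibble with columns `titrant_conc` and `value`, ordered by
#'   concentration, with attributes `wavelength_nm` (the channel used),
#'   `base_value` (the base-spectrum readout, i.e. A0 or F0) and `source`.
#' @examples
#' s <- gen_quench(ground_truth(k_true = 1e5, noise_sd = 0, seed = 1))
#' r <- readout_at(s)
#' attr(r, "base_value")  # F0
#' r
#' @export
readout_at <- function(series, policy = readout_policy()) {
  stopifnot(is_titration_series(series))
  if (!inherits(policy, "readout_policy")) stop_validation("`policy` must be a readout_policy.")
  grid <- series_grid(series)
  if (identical(policy$source, "peak_max")) {
    window <- policy$window %||% range(grid)
    if (window[1] < min(grid) || window[2] > max(grid)) {
      stop_range(sprintf(
        "Readout window [%g, %g] lies outside the wavelength grid [%g, %g].",
        window[1], window[2], min(grid), max(grid)
      ))
    }
    idx <- which(grid >= window[1] & grid <= window[2])
    if (!length(idx)) stop_range("Readout window contains no grid channel.")
    # which.max returns the first maximum: smallest-wavelength tie-break
    wl0 <- grid[idx[which.max(series$base$intensity[idx])]]
  } else {
    if (!policy$wavelength_nm %in% grid) {
      stop_range(sprintf("Wavelength %g nm is not a channel of the grid.", policy$wavelength_nm))
    }
    wl0 <- policy$wavelength_nm
  }
  pick <- if (policy$band_nm > 0) {
    which(abs(grid - wl0) <= policy$band_nm / 2)
  } else {
    which(grid == wl0)
  }
  read_one <- function(sp) mean(sp$intensity[pick])
  out <- tibble::tibble(
    titrant_conc = series$points$titrant_conc,
    value = purrr::map_dbl(series$points$spectrum, read_one)
  )
  attr(out, "wavelength_nm") <- wl0
  attr(out, "base_value") <- read_one(series$base)
  attr(out, "source") <- policy$source
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
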