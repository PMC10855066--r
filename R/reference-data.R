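#' Published reference binding parameters
#'
#' Reference constants reported for five pyrrolo[3,4-d]pyridazinone
#' derivatives (compounds 1-5) binding to calf thymus DNA and to the plasma
#' proteins alpha-1-acid glycoprotein (AAG) and gamma globulin (GG), shipped
#' as plain CSVs. These serve as inputs for recomputing derived quantities
#' (Gibbs energies, quenching rate constants, binding constants from their
#' logarithms, protection percentages) and as cross-checks for the package's
#' arithmetic.
#'
#' Available datasets:
#' * `"ctdna_uvvis"`: UV-Vis titration results per compound — apparent
#'   association constant `kapp_m1` (1/M), Gibbs energy `dg_jmol` (J/mol) and
#'   chromism magnitude `percent_h` (%).
#' * `"eb_displacement"`: ethidium bromide displacement — Stern-Volmer
#'   constant `ksv_m1` (1/M) and maximum percent exchange `percent_ex`.
#' * `"ki_protection"`: iodide quenching of each fluorescent compound with
#'   and without DNA — `ksv_absent_m1`, `ksv_present_m1` (1/M) and the
#'   percent reduction.
#' * `"protein_binding"`: per protein, compound and temperature —
#'   Stern-Volmer constant `ksv_e4` (1e4/M) with standard error, quenching
#'   rate constant `kq_e12` (1e12/(M s)), `log_kb`, binding constant `kb_e4`
#'   (1e4/M), site number `n`, and (at 297 K) `dg_kjmol`, `dh_kjmol`
#'   (kJ/mol) and `ds_jmolk` (J/(mol K)).
#'
#' @param name One of the dataset names above.
#' @return A tibble.
#' @examples
#' reference_dataset("ctdna_uvvis")
#' @export
reference_dataset <- function(name = c("ctdna_uvvis", "eb_displacement",
                                       "ki_protection", "protein_binding")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "specbind",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
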