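#' Aggregate a binding-mode verdict from assay classifications
#'
#' Formalizes the qualitative reasoning used to call a DNA binding mode from
#' converging spectroscopic evidence, as a deterministic majority rule with
#' a veto: intercalation is only called when both the apparent-constant test
#' and the iodide-protection test point to it; an electrostatic component
#' reported by the ionic-strength assay annotates (or, in the absence of any
#' groove-consistent evidence, becomes) the verdict; otherwise
#' groove-consistent votes (low apparent constant, weak iodide protection,
#' no salt release) are counted against intercalation-consistent votes
#' (probe displacement above the flag threshold).
#'
#' @param uvvis_mode Classification from [classify_uvvis_mode()]
#'   (`"groove_or_mixed"` / `"intercalation_likely"`), or `NULL` if the assay
#'   was not run.
#' @param ki_class Classification from [ki_protection()], or `NULL`.
#' @param ionic_class Classification from [ionic_strength_trend()], or
#'   `NULL`.
#' @param displacement_max Maximum percent exchange from [displacement()],
#'   or `NULL`.
#' @param displacement_flag Percent exchange above which displacement counts
#'   as intercalation-consistent (default 20).
#' @return A `binding_verdict` object: `$mode` (one of
#'   `"minor_groove_dominant"`, `"mixed"`, `"intercalation"`,
#'   `"electrostatic"`), `$electrostatic` (annotation flag) and `$evidence`
#'   (a tibble of test name / classification / vote).
#' @examples
#' # weak constant, weak protection, fluorescence falls with salt
#' binding_verdict(uvvis_mode = "groove_or_mixed", ki_class = "groove_or_mixed",
#'                 ionic_class = "no_electrostatic", displacement_max = 24.7)
#' @export
binding_verdict <- function(uvvis_mode = NULL, ki_class = NULL,
                            ionic_class = NULL, displacement_max = NULL,
                            displacement_flag = 20) {
  ev <- list()
  groove <- 0L; intercal <- 0L
  if (!is.null(uvvis_mode)) {
    vote <- if (uvvis_mode == "intercalation_likely") "intercalation" else "groove"
    if (vote == "groove") groove <- groove + 1L else intercal <- intercal + 1L
    ev <- c(ev, list(c("uvvis_kapp", uvvis_mode, vote)))
  }
  if (!is.null(ki_class)) {
    vote <- if (ki_class == "intercalation_protective") "intercalation" else "groove"
    if (vote == "groove") groove <- groove + 1L else intercal <- intercal + 1L
    ev <- c(ev, list(c("ki_protection", ki_class, vote)))
  }
  electro <- isTRUE(!is.null(ionic_class) && ionic_class == "electrostatic_component")
  if (!is.null(ionic_class)) {
    vote <- if (electro) "electrostatic" else "groove"
    if (vote == "groove") groove <- groove + 1L
    ev <- c(ev, list(c("ionic_strength", ionic_class, vote)))
  }
  if (!is.null(displacement_max)) {
    over <- displacement_max > displacement_flag
    if (over) intercal <- intercal + 1L
    ev <- c(ev, list(c("eb_displacement",
                       sprintf("max %%Ex = %.2f", displacement_max),
                       if (over) "intercalation" else "none")))
  }
  if (!length(ev)) stop_validation("No evidence supplied to binding_verdict().")
  both_intercal <- isTRUE(!is.null(uvvis_mode) && uvvis_mode == "intercalation_likely") &&
    isTRUE(!is.null(ki_class) && ki_class == "intercalation_protective")
  mode <- if (both_intercal) {
    "intercalation"
  } else if (electro) {
    if (groove == 0L) "electrostatic" else "mixed"
  } else if (groove > intercal) {
    "minor_groove_dominant"
  } else {
    "mixed"
  }
  evidence <- tibble::tibble(
    test = purrr::map_chr(ev, 1),
    classification = purrr::map_chr(ev, 2),
    vote = purrr::map_chr(ev, 3)
  )
  structure(list(mode = mode, electrostatic = electro, evidence = evidence),
            class = "binding_verdict")
}

#' @export
print.binding_verdict <- function(x, ...) {
  cat(sprintf("<binding verdict: %s%s>\n", x$mode,
              if (x$electrostatic) " (electrostatic component)" else ""))
  print(x$evidence)
  invisible(x)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the configured assays — UV-Vis association, probe displacement,
#' iodide protection, ionic-strength trend and multi-temperature protein
#' quenching with thermodynamics — and aggregates a DNA binding-mode
#' verdict. Every referenced input path is validated before any computation;
#' an error inside one assay aborts that assay only and is recorded in the
#' bundle. Re-running an identical configuration yields byte-identical JSON
#' (no timestamps enter the report).
#'
#' The configuration is a named list (or path to a JSON file) with entries:
#' * `assays`: a list; each element has `name`, `type` (one of `"uvvis"`,
#'   `"eb_displacement"`, `"ki_quench"`, `"ionic_strength"`,
#'   `"protein_quench"`), input path(s) (`input`; `input_absent` and
#'   `input_present` for `"ki_quench"`; for `"protein_quench"` a list
#'   `inputs` of `{path, temperature_k}`), `layout` (default `"long"`),
#'   optional `temperature_k`, `tau0`, and `readout`
#'   (`{source, wavelength_nm, window}`).
#' * `thresholds` (all optional): `kapp_lower`, `kapp_upper`,
#'   `kq_dynamic_limit`, `ki_reduction`, `displacement_flag`.
#' * `out_dir` (optional): where JSON and CSV reports are written.
#' * `seed` (optional): recorded in the bundle; the analysis itself is
#'   deterministic.
#'
#' @param config A named list or a path to a JSON configuration file.
#' @return A `report_bundle`: `$results` (one named element per assay),
#'   `$verdict` (a [binding_verdict()] if any DNA assay ran), `$errors`
#'   (named list of per-assay failure messages), `$config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_validation(sprintf("Config file does not exist: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (!is.list(config) || is.null(config$assays) || !length(config$assays)) {
    stop_validation("Config must be a list with a non-empty `assays` entry.")
  }
  th <- modifyList(list(kapp_lower = 1e4, kapp_upper = 1e5,
                        kq_dynamic_limit = 2e10, ki_reduction = 45,
                        displacement_flag = 20),
                   config$thresholds %||% list())
  if (any(unlist(th) <= 0)) stop_validation("All thresholds must be positive.")

  # validate every referenced path before any computation
  for (a in config$assays) {
    paths <- unlist(c(a[["input"]], a[["input_absent"]], a[["input_present"]],
                      purrr::map(a[["inputs"]] %||% list(), "path")))
    for (p in paths) {
      if (!file.exists(p)) {
        stop_validation(sprintf("Assay `%s`: input path does not exist: %s",
                                a$name %||% a$type, p))
      }
    }
  }

  results <- list(); errors <- list()
  for (a in config$assays) {
    nm <- a$name %||% a$type
    res <- tryCatch(run_assay(a, th),
                    error = function(e) structure(conditionMessage(e), class = "assay_error"))
    if (inherits(res, "assay_error")) {
      errors[[nm]] <- unclass(res)
      message(sprintf("Assay `%s` failed: %s", nm, res))
    } else {
      results[[nm]] <- res
    }
  }

  verdict <- verdict_from_results(results, th)
  bundle <- structure(list(results = results, verdict = verdict,
                           errors = errors, config = config,
                           thresholds = th, seed = config$seed %||% NA),
                      class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

read_policy_cfg <- function(cfg) {
  if (is.null(cfg)) return(readout_policy())
  readout_policy(source = cfg$source %||% "peak_max",
                 wavelength_nm = cfg$wavelength_nm,
                 window = if (!is.null(cfg$window)) as.numeric(unlist(cfg$window)),
                 band_nm = cfg$band_nm %||% 0)
}

run_assay <- function(a, th) {
  type <- match.arg(a$type, c("uvvis", "eb_displacement", "ki_quench",
                              "ionic_strength", "protein_quench"))
  pol <- read_policy_cfg(a$readout)
  layout <- a$layout %||% "long"
  tK <- a$temperature_k %||% 297
  switch(type,
    uvvis = {
      s <- read_series(a$input, layout = layout, mode = "absorbance",
                       assay = "uvvis_dna", temperature_k = tK)
      fit <- benesi_hildebrand(s, policy = pol)
      r <- readout_at(s, pol)
      ch <- chromism(attr(r, "base_value"), tail(r$value, 1))
      cls <- classify_uvvis_mode(fit, lower = th$kapp_lower, upper = th$kapp_upper)
      message(sprintf("[uvvis] Kapp = %.4g -> %s", fit$kapp, cls$mode))
      list(type = type, fit = fit,
           table = tibble::tibble(kapp_m1 = fit$kapp,
                                  dg_jmol = gibbs_from_k(fit$kapp, s$temperature_k),
                                  percent_h = ch$magnitude,
                                  direction = ch$direction,
                                  mode = cls$mode,
                                  indeterminate = cls$indeterminate))
    },
    eb_displacement = {
      s <- read_series(a$input, layout = layout, mode = "fluorescence",
                       assay = "eb_displacement", temperature_k = tK)
      disp <- displacement(s, policy = pol)
      sv <- stern_volmer(s, policy = pol, tau0 = a$tau0 %||% 6e-9)
      message(sprintf("[eb_displacement] max %%Ex = %.2f", attr(disp, "max_percent")))
      list(type = type, displacement = disp, fit = sv,
           table = tibble::tibble(ksv_m1 = sv$ksv,
                                  max_percent_ex = attr(disp, "max_percent")))
    },
    ki_quench = {
      sa <- read_series(a$input_absent, layout = layout, mode = "fluorescence",
                        assay = "ki_quench", temperature_k = tK)
      sp <- read_series(a$input_present, layout = layout, mode = "fluorescence",
                        assay = "ki_quench", temperature_k = tK)
      fa <- stern_volmer(sa, policy = pol)
      fp <- stern_volmer(sp, policy = pol)
      prot <- ki_protection(fa, fp, threshold = th$ki_reduction)
      message(sprintf("[ki_quench] reduction = %.1f%% -> %s",
                      prot$reduction_percent, prot$classification))
      list(type = type, fit_absent = fa, fit_present = fp, table = prot)
    },
    ionic_strength = {
      s <- read_series(a$input, layout = layout, mode = "fluorescence",
                       assay = "ionic_strength", temperature_k = tK)
      tr <- ionic_strength_trend(s, policy = pol)
      message(sprintf("[ionic_strength] slope = %.3g -> %s", tr$slope, tr$classification))
      list(type = type, table = tr)
    },
    protein_quench = {
      tau0 <- a$tau0 %||% 6e-9
      series <- purrr::map(a$inputs, function(inp) {
        read_series(inp$path, layout = layout, mode = "fluorescence",
                    assay = "protein_quench",
                    temperature_k = inp$temperature_k %||% tK)
      })
      sv <- purrr::map(series, stern_volmer, policy = pol, tau0 = tau0)
      dl <- purrr::map(series, double_log_fit, policy = pol)
      mech <- quench_mechanism(sv[[1]], fits_by_t = sv,
                               dynamic_limit = th$kq_dynamic_limit)
      thermo <- vant_hoff(dl)
      gr <- gibbs_report(thermo)
      forces <- interaction_forces(thermo$dh, thermo$ds)
      message(sprintf("[protein_quench] mechanism = %s; dH = %.4g kJ/mol, dS = %.4g -> %s",
                      mech$mechanism, thermo$dh / 1e3, thermo$ds, forces))
      per_t <- tibble::tibble(
        temperature_k = purrr::map_dbl(sv, "temperature_k"),
        ksv = purrr::map_dbl(sv, "ksv"),
        kq = purrr::map_dbl(sv, "kq"),
        log_kb = purrr::map_dbl(dl, "log_kb"),
        kb = purrr::map_dbl(dl, "kb"),
        n = purrr::map_dbl(dl, "n")
      )
      list(type = type, quench_fits = sv, binding_fits = dl,
           thermo = thermo, mechanism = mech, gibbs = gr, forces = forces,
           table = per_t)
    }
  )
}

verdict_from_results <- function(results, th) {
  uvvis <- purrr::detect(results, function(r) r$type == "uvvis")
  ki <- purrr::detect(results, function(r) r$type == "ki_quench")
  ionic <- purrr::detect(results, function(r) r$type == "ionic_strength")
  eb <- purrr::detect(results, function(r) r$type == "eb_displacement")
  if (is.null(uvvis) && is.null(ki) && is.null(ionic) && is.null(eb)) return(NULL)
  binding_verdict(
    uvvis_mode = if (!is.null(uvvis)) uvvis$table$mode,
    ki_class = if (!is.null(ki)) ki$table$classification,
    ionic_class = if (!is.null(ionic)) ionic$table$classification,
    displacement_max = if (!is.null(eb)) eb$table$max_percent_ex,
    displacement_flag = th$displacement_flag
  )
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    seed = bundle$seed,
    thresholds = bundle$thresholds,
    results = purrr::map(bundle$results, function(r) {
      c(list(type = r$type), list(table = r$table))
    }),
    verdict = if (!is.null(bundle$verdict)) {
      list(mode = bundle$verdict$mode,
           electrostatic = bundle$verdict$electrostatic,
           evidence = bundle$verdict$evidence)
    },
    errors = bundle$errors
  )
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  for (nm in names(bundle$results)) {
    readr::write_csv(bundle$results[[nm]]$table,
                     file.path(out_dir, paste0(nm, ".csv")), progress = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report bundle: %d assay(s), %d error(s)>\n",
              length(x$results), length(x$errors)))
  for (nm in names(x$results)) {
    cat("--", nm, "(", x$results[[nm]]$type, ")\n")
    print(x$results[[nm]]$table)
  }
  if (!is.null(x$verdict)) print(x$verdict)
  invisible(x)
}
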