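# Orchestration: run the full analysis on one regeneration experiment
# (in-memory synthetic bundle or a file-based run configuration) and
# compare the resulting metrics across experimental conditions.

.pipeline_version <- function() {
  as.character(utils::packageVersion("nadhreg"))
}

.config_digest <- function(x) {
  # small structural digest so reports are self-describing without
  # depending on a hashing package
  s <- paste(deparse(x, control = "all"), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)) %%
            .Machine$integer.max)
}

#' Run the full regeneration analysis
#'
#' Executes the pipeline stages in experiment order: sweep segmentation
#' and peak detection on the pre-regeneration voltammogram (kinetics fit
#' when voltammograms at several scan rates are available), charge
#' integration of the chronoamperogram, optional equivalent-circuit
#' fitting of an impedance spectrum, assay quantification of active
#' 1,4-NADH, and the derived regeneration metrics.  Failures in optional
#' stages (kinetics, impedance) degrade to notices; failures in required
#' stages (charge, assay) abort.
#'
#' @param x a `nadh_bundle` from [make_bundle()], or the path to a YAML
#'   run-configuration file (see [read_run_config()]).
#' @param peak_window cathodic peak search window in V (default
#'   `c(-1.4, -0.8)`).
#' @param selectivity_mode denominator of the selectivity:
#'   `"B_minus_A"` (340 nm extinction of the regenerated solution minus
#'   the pre-regeneration electrolyte at equal dilution, the default) or
#'   `"D_minus_E_uncorrected"` (the raw D-E difference).
#' @param strict_rh_offset passed to [quantify_nadh()].
#' @param z electrons per regenerated 1,4-NADH (default 2).
#' @param eis_candidates list of `circuit_model`s to rank against an
#'   attached impedance spectrum (default: the four presets).
#' @param ... reserved.
#' @return An object of class `run_report` with elements `peaks`,
#'   `kinetics`, `q_total`, `assay`, `metrics`, `eis_fits`, `conditions`,
#'   `provenance` and `notices`.
#' @export
run_analysis <- function(x, peak_window = c(-1.4, -0.8),
                         selectivity_mode = c("B_minus_A",
                                              "D_minus_E_uncorrected"),
                         strict_rh_offset = TRUE, z = 2,
                         eis_candidates = NULL, ...) {
  selectivity_mode <- match.arg(selectivity_mode)
  if (is.character(x) && length(x) == 1) {
    x <- .bundle_from_config(read_run_config(x))
  }
  stopifnot(inherits(x, "nadh_bundle"))
  notices <- character(0)

  # --- voltammetry stage (optional) ---------------------------------
  peaks <- NULL; kinetics <- NULL
  vr <- tryCatch({
    segs <- segment_sweeps(x$cv_pre)
    cath <- segs[[which(vapply(segs, `[[`, "", "direction") ==
                          "cathodic")[1]]]
    detect_peaks(cath, search_window = peak_window)
  }, error = function(e) conditionMessage(e))
  if (is.character(vr)) {
    notices <- c(notices, paste("voltammetry stage skipped:", vr))
  } else if (length(vr) == 0) {
    notices <- c(notices, "voltammetry stage: no cathodic peak in window")
  } else {
    peaks <- vr
  }
  if (!is.null(x$cv_series) && length(x$cv_series) >= 2) {
    kr <- tryCatch({
      pts <- do.call(rbind, lapply(x$cv_series, function(cv) {
        segs <- segment_sweeps(cv)
        cath <- segs[[which(vapply(segs, `[[`, "", "direction") ==
                              "cathodic")[1]]]
        pk <- detect_peaks(cath, search_window = peak_window)
        data.frame(nu = cv$scan_rate, E_p = pk[[1]]$E_p)
      }))
      peak_shift_fit(pts, temperature = x$cv_series[[1]]$temperature)
    }, error = function(e) conditionMessage(e))
    if (is.character(kr)) {
      notices <- c(notices, paste("kinetics stage skipped:", kr))
    } else {
      kinetics <- kr
    }
  }

  # --- impedance stage (optional) -----------------------------------
  eis_fits <- NULL
  if (!is.null(x$eis)) {
    if (is.null(eis_candidates)) {
      eis_candidates <- lapply(c("EEC_A", "EEC_B", "EEC_C", "EEC_D"),
                               eec_preset)
    }
    er <- tryCatch(select_model(x$eis$spectrum, eis_candidates),
                   error = function(e) conditionMessage(e))
    if (is.character(er)) {
      notices <- c(notices, paste("impedance stage skipped:", er))
    } else {
      eis_fits <- er
    }
  } else {
    notices <- c(notices, "no impedance spectrum attached")
  }

  # --- required stages: charge + assay ------------------------------
  q_total <- tryCatch(integrate_charge(x$chrono), error = function(e) {
    .nadhreg_error(paste("charge stage failed:", conditionMessage(e)),
                   "nadhreg_stage_error")
  })
  assay <- tryCatch(
    quantify_nadh(x$assay$set, x$assay$cal_nadh_340, x$assay$cal_rh_340,
                  x$assay$cal_rh_430, strict_rh_offset = strict_rh_offset),
    error = function(e) {
      .nadhreg_error(paste("assay stage failed:", conditionMessage(e)),
                     "nadhreg_stage_error")
    })
  ext_total <- switch(selectivity_mode,
    B_minus_A = x$assay$set$ext_340[["B"]] - x$assay$set$ext_340[["A"]],
    D_minus_E_uncorrected = x$assay$set$ext_340[["D"]] -
      x$assay$set$ext_340[["E"]])
  # selectivity compares undiluted NAD-species extinctions; the assay's
  # active extinction and the B-A difference share the 0.8 dilution
  metrics <- regen_metrics(assay, ext_total, x$chrono,
                           volume = x$config$volume, area = x$config$area,
                           duration = x$config$duration, z = z)
  structure(
    list(peaks = peaks, kinetics = kinetics, q_total = q_total,
         assay = assay, metrics = metrics, eis_fits = eis_fits,
         conditions = x$conditions,
         provenance = list(version = .pipeline_version(),
                           seed = x$truth$seed,
                           config_digest = .config_digest(x$config)),
         notices = notices),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$peaks)) {
    cat(sprintf("  cathodic peak: E_p = %.4f V, i_p = %.3e A\n",
                x$peaks[[1]]$E_p, x$peaks[[1]]$i_p))
  }
  if (!is.null(x$kinetics)) {
    cat(sprintf("  kinetics: alpha*n = %.3f\n", x$kinetics$alpha_n))
  }
  cat(sprintf("  Q_total = %.4g C, c(1,4-NADH) = %.4g mM\n",
              x$q_total, x$assay$c_nadh))
  cat(sprintf("  selectivity = %.3f, eta_F = %.3f, rate = %.4g umol/h/cm2\n",
              x$metrics$selectivity, x$metrics$eta_f,
              x$metrics$production_rate))
  if (!is.null(x$eis_fits)) {
    cat(sprintf("  best EEC: %s\n",
                attr(x$eis_fits[[1]]$circuit, "preset")))
  }
  for (n in x$notices) cat("  notice:", n, "\n")
  invisible(x)
}

#' Compare run reports along one condition axis
#'
#' Builds a long-format table of selectivity, Faraday efficiency and
#' specific production rate against the chosen condition axis.  All other
#' condition labels must agree across the reports.  For a time axis the
#' metrics are per-interval values (each report describes its own
#' interval), matching the interval semantics of time-series regeneration
#' experiments.
#'
#' @param reports list of `run_report`s (>= 2).
#' @param axis `"potential"`, `"pH"` or `"time"`.
#' @return A data frame with columns `condition` (axis value),
#'   `selectivity`, `eta_f`, `production_rate`, sorted along the axis.
#' @export
compare_conditions <- function(reports, axis = c("potential", "pH", "time")) {
  axis <- match.arg(axis)
  if (!is.list(reports) || length(reports) < 2) {
    .nadhreg_error("need at least 2 reports to compare",
                   "nadhreg_insufficient_data")
  }
  stopifnot(all(vapply(reports, inherits, TRUE, "run_report")))
  conds <- lapply(reports, `[[`, "conditions")
  axis_vals <- vapply(conds, function(cc) {
    if (is.null(cc[[axis]])) {
      .nadhreg_error(sprintf("a report lacks the '%s' condition label", axis),
                     "nadhreg_incompatible")
    }
    as.numeric(cc[[axis]])
  }, numeric(1))
  other <- setdiff(unique(unlist(lapply(conds, names))), axis)
  diffs <- character(0)
  for (lab in other) {
    vals <- lapply(conds, `[[`, lab)
    if (length(unique(vapply(vals, function(v)
      paste(format(v), collapse = "/"), ""))) > 1) {
      diffs <- c(diffs, lab)
    }
  }
  if (length(diffs)) {
    .nadhreg_error(sprintf(
      "reports differ in condition label(s) besides '%s': %s",
      axis, paste(diffs, collapse = ", ")), "nadhreg_incompatible")
  }
  tab <- data.frame(
    condition = axis_vals,
    selectivity = vapply(reports, function(r) r$metrics$selectivity,
                         numeric(1)),
    eta_f = vapply(reports, function(r) r$metrics$eta_f, numeric(1)),
    production_rate = vapply(reports, function(r) r$metrics$production_rate,
                             numeric(1)))
  tab <- tab[order(tab$condition), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "axis") <- axis
  tab
}

# ---------------------------------------------------------------------
# report serialization

.report_to_list <- function(report) {
  list(
    peaks = if (is.null(report$peaks)) NULL else
      lapply(report$peaks, function(p)
        list(E_p = p$E_p, i_p = p$i_p, direction = p$direction,
             prominence = p$prominence)),
    kinetics = if (is.null(report$kinetics)) NULL else
      unclass(report$kinetics),
    q_total = report$q_total,
    assay = unclass(report$assay),
    metrics = unclass(report$metrics),
    eis = if (is.null(report$eis_fits)) NULL else
      lapply(report$eis_fits, function(f)
        list(preset = attr(f$circuit, "preset"),
             params = as.list(f$params), se = as.list(f$se),
             residual_norm = f$residual_norm, aicc = f$aicc,
             c_eff = as.list(f$c_eff))),
    conditions = report$conditions,
    provenance = report$provenance,
    notices = report$notices)
}

#' Write / read a machine-readable run report
#'
#' Serializes the numeric content of a `run_report` (peaks, kinetics,
#' charge, assay result, metrics, circuit fits, condition labels,
#' provenance) as JSON at full double precision, and reads it back.  The
#' reread report carries class `run_report` and supports
#' [compare_conditions()].
#'
#' @param report a `run_report`.
#' @param path output / input file path.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   a `run_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(.report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  metrics <- raw$metrics
  class(metrics) <- "regen_metrics"
  assay <- raw$assay
  class(assay) <- "assay_result"
  structure(
    list(peaks = raw$peaks,
         kinetics = if (!is.null(raw$kinetics)) {
           k <- raw$kinetics; class(k) <- "kinetics_fit"; k
         },
         q_total = raw$q_total, assay = assay, metrics = metrics,
         eis_fits = raw$eis, conditions = as.list(raw$conditions),
         provenance = raw$provenance, notices = raw$notices),
    class = "run_report")
}

# ---------------------------------------------------------------------
# file-based run configuration

#' Read a YAML run configuration
#'
#' The configuration names the delimited-text inputs of one regeneration
#' run and the analysis choices.  Recognised top-level fields:
#'
#' * `chrono`: list with `path`, `column_map` (named `time`, `current`),
#'   optional `units`, `applied_potential` — required.
#' * `assay`: `path` to a CSV with columns `solution` (A..E),
#'   `wavelength` (340/430), `extinction` — required.
#' * `calibration`: `path` to a CSV with columns `species`
#'   (`NADH`/`Rh`), `wavelength`, `concentration`, `extinction` — required.
#' * `cv_pre`: list with `path`, `column_map` (named `potential`,
#'   `current`), optional `units`, `scan_rate` — optional.
#' * `eis`: list with `path`, `column_map` (named `frequency`, `z_re`,
#'   `z_im`), optional `bias_potential` — optional.
#' * `volume` (L), `area` (cm^2), `duration` (s), `conditions` (named
#'   labels), `seed`.
#'
#' Relative paths are resolved against the configuration file's
#' directory.  Referenced files must exist at load time.
#'
#' @param path path to the YAML file.
#' @return A validated configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p)) {
      .nadhreg_error(sprintf("configured file does not exist: %s", p),
                     "nadhreg_input_error")
    }
    p
  }
  for (req in c("chrono", "assay", "calibration")) {
    if (is.null(cfg[[req]])) {
      .nadhreg_error(sprintf("run configuration lacks required '%s' entry",
                             req), "nadhreg_input_error")
    }
  }
  cfg$chrono$path <- resolve(cfg$chrono$path)
  cfg$assay$path <- resolve(cfg$assay$path)
  cfg$calibration$path <- resolve(cfg$calibration$path)
  if (!is.null(cfg$cv_pre)) cfg$cv_pre$path <- resolve(cfg$cv_pre$path)
  if (!is.null(cfg$eis)) cfg$eis$path <- resolve(cfg$eis$path)
  if (is.null(cfg$volume) || is.null(cfg$area)) {
    .nadhreg_error("run configuration needs 'volume' (L) and 'area' (cm^2)",
                   "nadhreg_input_error")
  }
  structure(cfg, class = "run_config")
}

# assemble an in-memory bundle-shaped object from a file configuration
.bundle_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cm <- function(x, default) if (is.null(x)) default else unlist(x)
  chrono <- read_electrochem_table(
    cfg$chrono$path, "chrono",
    column_map = cm(cfg$chrono$column_map, c(time = "time",
                                             current = "current")),
    units = if (!is.null(cfg$chrono$units)) unlist(cfg$chrono$units),
    applied_potential = if (!is.null(cfg$chrono$applied_potential))
      cfg$chrono$applied_potential else NA_real_)
  atab <- utils::read.csv(cfg$assay$path, stringsAsFactors = FALSE)
  need <- c("solution", "wavelength", "extinction")
  if (!all(need %in% names(atab))) {
    .nadhreg_error("assay table needs columns solution, wavelength, extinction",
                   "nadhreg_format_error")
  }
  if (!is.numeric(atab$extinction)) {
    .nadhreg_error("assay extinctions must be numeric", "nadhreg_parse_error")
  }
  pick <- function(wl) {
    sel <- atab$wavelength == wl
    stats::setNames(atab$extinction[sel], atab$solution[sel])
  }
  set <- assay_solution_set(pick(340), pick(430))
  ctab <- utils::read.csv(cfg$calibration$path, stringsAsFactors = FALSE)
  calfor <- function(sp, wl) {
    sel <- ctab$species == sp & ctab$wavelength == wl
    if (sum(sel) < 2) {
      .nadhreg_error(sprintf("calibration series %s@%d missing", sp, wl),
                     "nadhreg_input_error")
    }
    fit_calibration(ctab$concentration[sel], ctab$extinction[sel], sp, wl)
  }
  cv_pre <- NULL
  if (!is.null(cfg$cv_pre)) {
    cv_pre <- read_electrochem_table(
      cfg$cv_pre$path, "cv",
      column_map = cm(cfg$cv_pre$column_map, c(potential = "potential",
                                               current = "current")),
      units = if (!is.null(cfg$cv_pre$units)) unlist(cfg$cv_pre$units),
      scan_rate = cfg$cv_pre$scan_rate)
  }
  eis <- NULL
  if (!is.null(cfg$eis)) {
    spec <- read_electrochem_table(
      cfg$eis$path, "eis",
      column_map = cm(cfg$eis$column_map, c(frequency = "frequency",
                                            z_re = "z_re", z_im = "z_im")),
      bias_potential = if (!is.null(cfg$eis$bias_potential))
        cfg$eis$bias_potential else NA_real_)
    eis <- list(spectrum = spec)
  }
  duration <- if (!is.null(cfg$duration)) cfg$duration else chrono$duration
  structure(
    list(cv_pre = cv_pre, chrono = chrono, cv_post = NULL,
         assay = list(set = set,
                      cal_nadh_340 = calfor("NADH", 340),
                      cal_rh_340 = calfor("Rh", 340),
                      cal_rh_430 = calfor("Rh", 430)),
         eis = eis,
         conditions = if (is.null(cfg$conditions)) list() else
           cfg$conditions,
         config = list(volume = cfg$volume, area = cfg$area,
                       duration = duration, file_config = unclass(cfg)),
         truth = list(seed = if (is.null(cfg$seed)) NA_integer_ else
           cfg$seed)),
    class = "nadh_bundle")
}

#' Write the assay and calibration tables of a bundle to CSV
#'
#' Companion writers so a synthetic bundle can be exported to the same
#' delimited formats the file-based configuration reads.
#'
#' @param bundle a `nadh_bundle`.
#' @param assay_path,calibration_path output CSV paths.
#' @return A named list of the written paths, invisibly.
#' @export
write_assay_tables <- function(bundle, assay_path, calibration_path) {
  set <- bundle$assay$set
  atab <- rbind(
    data.frame(solution = names(set$ext_340), wavelength = 340,
               extinction = as.numeric(set$ext_340)),
    data.frame(solution = names(set$ext_430), wavelength = 430,
               extinction = as.numeric(set$ext_430)))
  utils::write.csv(atab, assay_path, row.names = FALSE, quote = FALSE)
  # re-emit calibration points from the fitted lines' own inputs is not
  # possible (only the fits are kept), so export exact points on the lines
  cal <- function(fit, sp, conc) {
    data.frame(species = sp, wavelength = fit$wavelength,
               concentration = conc,
               extinction = fit$m * conc + fit$b)
  }
  ctab <- rbind(
    cal(bundle$assay$cal_nadh_340, "NADH", seq(0, 0.25, by = 0.05)),
    cal(bundle$assay$cal_rh_340, "Rh", seq(0, 0.5, by = 0.1)),
    cal(bundle$assay$cal_rh_430, "Rh", seq(0, 0.5, by = 0.1)))
  utils::write.csv(ctab, calibration_path, row.names = FALSE, quote = FALSE)
  invisible(list(assay = assay_path, calibration = calibration_path))
}
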