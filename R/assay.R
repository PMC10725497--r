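# Two-wavelength enzyme-assay quantification of active 1,4-NADH and the
# derived regeneration metrics.
#
# The assay measures UV-Vis extinctions of five solutions (A-E) prepared
# from the regeneration electrolyte at a fixed 0.8 dilution.  Solution D
# contains the regenerated mixture before, and solution E after, the
# lactate-dehydrogenase step that consumes exactly the enzymatically
# active 1,4-NADH.  Only the rhodium mediator absorbs at 430 nm, so the
# 430 nm difference D - E isolates any mediator change between the two
# cuvettes; after subtracting its 340 nm contribution, the remaining
# D - E extinction at 340 nm belongs to active 1,4-NADH alone.

.DILUTION <- 0.8

#' Linear extinction-vs-concentration calibration
#'
#' Ordinary least-squares line `extinction = m * c + b` for one species at
#' one wavelength.
#'
#' @param concentrations concentrations in mM (>= 2 distinct values).
#' @param extinctions measured extinctions, same length.
#' @param species label, e.g. `"1,4-NADH"` or `"Rh-complex"`.
#' @param wavelength wavelength label in nm (340 or 430).
#' @return An object of class `calibration_curve` with `m` (extinction per
#'   mM), `b`, `r_squared`, `n_points`, `species`, `wavelength` and
#'   `usable` (`FALSE` when the slope is not positive).
#' @export
fit_calibration <- function(concentrations, extinctions,
                            species = "1,4-NADH", wavelength = 340) {
  conc <- as.numeric(concentrations); ext <- as.numeric(extinctions)
  if (length(conc) != length(ext)) {
    .nadhreg_error("concentrations and extinctions must have equal length",
                   "nadhreg_format_error")
  }
  if (length(unique(conc)) < 2) {
    .nadhreg_error("need at least 2 distinct concentrations",
                   "nadhreg_rank_deficient")
  }
  fit <- stats::lm(ext ~ conc)
  m <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  sst <- sum((ext - mean(ext))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(
    list(m = m, b = b, r_squared = r2, n_points = length(conc),
         species = species, wavelength = wavelength, usable = m > 0),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s @ %g nm: Ext = %.4g * c + %.4g (R2 = %.4f)%s\n",
              x$species, x$wavelength, x$m, x$b,
              if (is.na(x$r_squared)) NaN else x$r_squared,
              if (x$usable) "" else "  [unusable: non-positive slope]"))
  invisible(x)
}

#' Extinctions of the five assay solutions
#'
#' Container for the 340 nm and 430 nm extinctions of solutions A-E:
#' A = diluted electrolyte (before regeneration), B = diluted regenerated
#' solution, C = regenerated solution + pyruvate, D = C re-measured after
#' E, E = regenerated solution + pyruvate + LDH (active 1,4-NADH consumed).
#' All solutions share the fixed 0.8 dilution.
#'
#' @param ext_340 named numeric vector of extinctions at 340 nm; names
#'   among `A`..`E`, `D` and `E` required.
#' @param ext_430 named numeric vector at 430 nm; `D` and `E` required.
#' @return An object of class `assay_solution_set`.
#' @export
assay_solution_set <- function(ext_340, ext_430) {
  for (w in c("340", "430")) {
    v <- if (w == "340") ext_340 else ext_430
    miss <- setdiff(c("D", "E"), names(v))
    if (length(miss)) {
      .nadhreg_error(sprintf("solution %s missing at %s nm",
                             paste(miss, collapse = ", "), w),
                     "nadhreg_input_error")
    }
    if (!all(is.finite(v))) {
      .nadhreg_error("extinctions must be finite", "nadhreg_input_error")
    }
  }
  structure(list(ext_340 = ext_340, ext_430 = ext_430,
                 dilution = .DILUTION),
            class = "assay_solution_set")
}

#' Active 1,4-NADH concentration from the assay solutions
#'
#' Inverts the Beer-Lambert model of the assay in four steps:
#' the mediator change between cuvettes D and E from the 430 nm
#' difference, `delta_c_Rh = ((D430 - E430)/0.8 - b_Rh430) / m_Rh430`;
#' its 340 nm contribution,
#' `dExt_Rh340 = (delta_c_Rh * m_Rh340 + b_Rh340) * 0.8`;
#' the active-species extinction,
#' `Ext_NADH340 = D340 - E340 - dExt_Rh340`; and finally
#' `c_NADH = (Ext_NADH340/0.8 - b_NADH340) / m_NADH340`.
#'
#' @param set an [assay_solution_set()].
#' @param cal_nadh_340 [fit_calibration()] curve of 1,4-NADH at 340 nm.
#' @param cal_rh_340 calibration of the Rh complex at 340 nm.
#' @param cal_rh_430 calibration of the Rh complex at 430 nm.
#' @param strict_rh_offset keep the 340 nm calibration offset in the mediator
#'   correction even when `delta_c_Rh = 0` (the correction formula as
#'   printed; default `TRUE`).  With `FALSE` the offset is dropped when
#'   `delta_c_Rh = 0`.
#' @return An object of class `assay_result` with `delta_c_rh` (mM),
#'   `d_ext_rh_340`, `ext_nadh_340`, `c_nadh` (mM) and a `warnings`
#'   vector.  A negative concentration is reported, not clamped, and
#'   always carries a warning.
#' @export
quantify_nadh <- function(set, cal_nadh_340, cal_rh_340, cal_rh_430,
                          strict_rh_offset = TRUE) {
  stopifnot(inherits(set, "assay_solution_set"))
  for (cal in list(cal_nadh_340, cal_rh_340, cal_rh_430)) {
    stopifnot(inherits(cal, "calibration_curve"))
  }
  if (cal_rh_430$m == 0 || cal_nadh_340$m == 0) {
    .nadhreg_error("calibration with zero slope is unusable",
                   "nadhreg_unusable_calibration")
  }
  dil <- set$dilution
  d430 <- set$ext_430[["D"]]; e430 <- set$ext_430[["E"]]
  d340 <- set$ext_340[["D"]]; e340 <- set$ext_340[["E"]]
  delta_c_rh <- ((d430 - e430) / dil - cal_rh_430$b) / cal_rh_430$m
  d_ext_rh_340 <-
    if (!strict_rh_offset && abs(delta_c_rh) < 1e-12) 0
    else (delta_c_rh * cal_rh_340$m + cal_rh_340$b) * dil
  ext_nadh_340 <- d340 - e340 - d_ext_rh_340
  c_nadh <- (ext_nadh_340 / dil - cal_nadh_340$b) / cal_nadh_340$m
  warnings <- character(0)
  if (c_nadh < 0) {
    warnings <- c(warnings,
                  "negative 1,4-NADH concentration: assay inconsistent (E exceeds D at 340 nm after mediator correction)")
  }
  structure(
    list(delta_c_rh = delta_c_rh, d_ext_rh_340 = d_ext_rh_340,
         ext_nadh_340 = ext_nadh_340, c_nadh = c_nadh,
         warnings = warnings),
    class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf(
    "<assay_result> c(1,4-NADH) = %.4g mM\n  delta_c_Rh = %.4g mM, dExt_Rh,340 = %.4g, Ext_NADH,340 = %.4g\n",
    x$c_nadh, x$delta_c_rh, x$d_ext_rh_340, x$ext_nadh_340))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Selectivity from 340 nm extinctions
#'
#' Fraction of the 340 nm absorbance of all NAD reduction products that is
#' due to active 1,4-NADH.  Values outside [0, 1] are clamped with a
#' warning (attribute `"warnings"`).
#'
#' @param ext_active_340 extinction at 340 nm attributable to active
#'   1,4-NADH.
#' @param ext_total_340 total 340 nm extinction of NAD2 and all NADH
#'   species (must be positive).
#' @return Selectivity in [0, 1].
#' @export
selectivity_from_extinctions <- function(ext_active_340, ext_total_340) {
  if (ext_total_340 <= 0) {
    .nadhreg_error("total 340 nm extinction must be positive: selectivity undefined",
                   "nadhreg_undefined_selectivity")
  }
  s <- ext_active_340 / ext_total_340
  warnings <- character(0)
  if (s < 0) { warnings <- "selectivity below 0 clamped"; s <- 0 }
  if (s > 1) { warnings <- "selectivity above 1 clamped"; s <- 1 }
  structure(s, warnings = warnings)
}

#' Total passed charge from a chronoamperogram
#'
#' Trapezoidal integral of the magnitude of the current over time.
#'
#' @param trace a [chronoamperogram()] with at least 2 samples.
#' @return Charge in coulombs.
#' @export
integrate_charge <- function(trace) {
  stopifnot(inherits(trace, "chronoamperogram"))
  if (length(trace$time) < 2) {
    .nadhreg_error("need at least 2 samples to integrate charge",
                   "nadhreg_insufficient_data")
  }
  pracma::trapz(trace$time, abs(trace$current))
}

#' Faraday efficiency of the regeneration
#'
#' `eta_F = Q_theo / Q_total` with `Q_theo = z * F * n_NADH` and `z = 2`
#' electrons per regenerated 1,4-NADH (hydride transfer: 2 e- + H+).
#'
#' @param c_nadh active 1,4-NADH concentration in mM.
#' @param volume solution volume in liters.
#' @param q_total total passed charge in coulombs (positive).
#' @param z electrons per regenerated molecule (fixed default 2).
#' @return A list with `eta_f`, `q_theo`, `q_total`, `n_nadh_mol` and
#'   `warnings` (`eta_f > 1` is allowed but flagged).
#' @export
faraday_efficiency <- function(c_nadh, volume, q_total, z = 2) {
  if (volume <= 0) {
    .nadhreg_error("volume must be positive", "nadhreg_domain_error")
  }
  if (q_total <= 0) {
    .nadhreg_error("total charge must be positive", "nadhreg_domain_error")
  }
  n_mol <- c_nadh * 1e-3 * volume        # mM * L -> mol
  q_theo <- z * FARADAY * n_mol
  eta <- q_theo / q_total
  warnings <- character(0)
  if (eta > 1) warnings <- "Faraday efficiency above 1: check assay or charge"
  list(eta_f = eta, q_theo = q_theo, q_total = q_total,
       n_nadh_mol = n_mol, warnings = warnings)
}

#' Specific production rate
#'
#' Regenerated amount per electrode area and time, in umol h^-1 cm^-2.
#'
#' @param n_nadh_mol regenerated 1,4-NADH in moles.
#' @param area electrode area in cm^2 (positive).
#' @param duration regeneration time in seconds (positive).
#' @return Rate in umol h^-1 cm^-2.
#' @export
production_rate <- function(n_nadh_mol, area, duration) {
  if (area <= 0 || duration <= 0) {
    .nadhreg_error("area and duration must be positive",
                   "nadhreg_domain_error")
  }
  n_nadh_mol * 1e6 / (area * duration / 3600)
}

#' Bundle the regeneration metrics for one run
#'
#' Convenience wrapper combining [selectivity_from_extinctions()],
#' [integrate_charge()], [faraday_efficiency()] and [production_rate()]
#' into one record.
#'
#' @param assay an `assay_result` from [quantify_nadh()].
#' @param ext_total_340 denominator extinction for the selectivity
#'   (340 nm absorbance of all NAD reduction products, e.g. `B340 - A340`).
#' @param trace a [chronoamperogram()] of the regeneration.
#' @param volume solution volume in liters.
#' @param area electrode area in cm^2.
#' @param duration regeneration duration in seconds (default: the trace's).
#' @param z electrons per regenerated molecule (default 2).
#' @return An object of class `regen_metrics` with `selectivity`, `eta_f`,
#'   `q_total`, `q_theo`, `n_nadh_mol`, `production_rate`
#'   (umol h^-1 cm^-2) and accumulated `warnings`.
#' @export
regen_metrics <- function(assay, ext_total_340, trace, volume, area,
                          duration = NULL, z = 2) {
  stopifnot(inherits(assay, "assay_result"))
  if (is.null(duration)) duration <- trace$duration
  sel <- selectivity_from_extinctions(assay$ext_nadh_340, ext_total_340)
  q_total <- integrate_charge(trace)
  fe <- faraday_efficiency(assay$c_nadh, volume, q_total, z = z)
  rate <- production_rate(max(fe$n_nadh_mol, 0), area, duration)
  structure(
    list(selectivity = as.numeric(sel), eta_f = fe$eta_f,
         q_total = q_total, q_theo = fe$q_theo,
         n_nadh_mol = fe$n_nadh_mol, production_rate = rate,
         electrode_area = area, duration = duration, volume = volume,
         warnings = c(assay$warnings, attr(sel, "warnings"), fe$warnings)),
    class = "regen_metrics")
}

#' @export
print.regen_metrics <- function(x, ...) {
  cat(sprintf(
    "<regen_metrics> selectivity = %.3f, eta_F = %.3f\n  Q_total = %.4g C, Q_theo = %.4g C, rate = %.4g umol/h/cm2\n",
    x$selectivity, x$eta_f, x$q_total, x$q_theo, x$production_rate))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
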