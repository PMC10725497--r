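# Tabular I/O and container types for potentiostat / spectrophotometer data.
# Sign convention throughout: cathodic (reduction) current is negative,
# potentials are quoted against Ag/AgCl.

.nadhreg_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "nadhreg_error"), call = call))
}

.unit_factors <- c(
  V = 1, mV = 1e-3, A = 1, mA = 1e-3, uA = 1e-6,
  s = 1, ms = 1e-3, Hz = 1, kHz = 1e3, ohm = 1, kohm = 1e3
)

.apply_unit <- function(x, unit) {
  if (is.null(unit) || is.na(unit)) return(x)
  if (!unit %in% names(.unit_factors)) {
    .nadhreg_error(sprintf("unknown unit '%s'", unit), "nadhreg_unit_error")
  }
  x * .unit_factors[[unit]]
}

#' Cyclic voltammogram container
#'
#' Holds one potential/current trace recorded under a triangular potential
#' programme, together with the scan rate, waveform vertices and condition
#' metadata.  Cathodic current is negative; potential is in volts vs
#' Ag/AgCl.
#'
#' @param potential numeric vector of electrode potentials (V).
#' @param current numeric vector of currents (A), same length as `potential`.
#' @param scan_rate scan rate nu in V/s (positive).
#' @param vertices ordered turning potentials of the waveform (V).  If
#'   `NULL` they are inferred from the direction reversals of `potential`.
#' @param temperature absolute temperature in kelvin (default 293).
#' @param electrode_area electrode area in cm^2 (`NA` if unknown).
#' @param metadata free-form named list of condition labels (buffer, pH,
#'   analyte concentrations in mM, ...).
#' @param tol monotonicity tolerance in volts: counter-movement up to `tol`
#'   within a sweep is treated as instrument jitter (default 1 mV).
#' @return An object of class `cyclic_voltammogram`.
#' @export
cyclic_voltammogram <- function(potential, current, scan_rate,
                                vertices = NULL, temperature = 293,
                                electrode_area = NA_real_,
                                metadata = list(), tol = 1e-3) {
  potential <- as.numeric(potential)
  current <- as.numeric(current)
  if (length(potential) != length(current)) {
    .nadhreg_error("potential and current must have equal length",
                   "nadhreg_format_error")
  }
  if (length(potential) < 3) {
    .nadhreg_error("a voltammogram needs at least 3 samples",
                   "nadhreg_insufficient_data")
  }
  if (anyNA(potential) || anyNA(current)) {
    .nadhreg_error("potential/current must be finite", "nadhreg_format_error")
  }
  if (!is.numeric(scan_rate) || length(scan_rate) != 1 || scan_rate <= 0) {
    .nadhreg_error("scan_rate must be a single positive number",
                   "nadhreg_domain_error")
  }
  if (temperature <= 0) {
    .nadhreg_error("temperature must be positive kelvin",
                   "nadhreg_domain_error")
  }
  if (!is.na(electrode_area) && electrode_area <= 0) {
    .nadhreg_error("electrode_area must be positive", "nadhreg_domain_error")
  }
  rev_idx <- .reversal_indices(potential, tol)
  if (is.null(vertices)) {
    vertices <- potential[c(1L, rev_idx, length(potential))]
  }
  structure(
    list(potential = potential, current = current, scan_rate = scan_rate,
         vertices = as.numeric(vertices), temperature = temperature,
         electrode_area = electrode_area, metadata = metadata, tol = tol),
    class = "cyclic_voltammogram"
  )
}

#' @export
print.cyclic_voltammogram <- function(x, ...) {
  cat(sprintf(
    "<cyclic_voltammogram> %d points, nu = %g V/s, T = %g K\n  waveform: %s V\n",
    length(x$potential), x$scan_rate, x$temperature,
    paste(signif(x$vertices, 3), collapse = " -> ")))
  invisible(x)
}

# Indices of direction reversals, jitter-tolerant: a reversal is declared at
# the running extremum once the trace has moved against the current
# direction by more than tol volts.
.reversal_indices <- function(potential, tol) {
  n <- length(potential)
  if (diff(range(potential)) <= tol) {
    .nadhreg_error("potential trace is constant within tolerance",
                   "nadhreg_degenerate_waveform")
  }
  rev_idx <- integer(0)
  dir <- 0L                      # +1 rising, -1 falling, 0 undetermined
  ext_val <- potential[1L]
  ext_idx <- 1L
  for (i in 2:n) {
    p <- potential[i]
    if (dir == 0L) {
      if (p > ext_val + tol) dir <- 1L
      if (p < ext_val - tol) dir <- -1L
      if (dir != 0L) { ext_val <- p; ext_idx <- i }
    } else if (dir == 1L) {
      if (p >= ext_val) { ext_val <- p; ext_idx <- i }
      else if (p < ext_val - tol) {
        rev_idx <- c(rev_idx, ext_idx); dir <- -1L
        ext_val <- p; ext_idx <- i
      }
    } else {
      if (p <= ext_val) { ext_val <- p; ext_idx <- i }
      else if (p > ext_val + tol) {
        rev_idx <- c(rev_idx, ext_idx); dir <- 1L
        ext_val <- p; ext_idx <- i
      }
    }
  }
  rev_idx
}

#' Split a voltammogram into monotonic sweep segments
#'
#' Partitions the trace at its direction reversals into sweeps tagged
#' cathodic-going (potential decreasing) or anodic-going.  The segments are
#' index-disjoint, so concatenating them restores the original trace.
#'
#' @param cv a [cyclic_voltammogram()].
#' @return A list of segments; each has elements `potential`, `current`,
#'   `direction` (`"cathodic"` or `"anodic"`), `indices`, and the parent's
#'   `scan_rate` and `temperature`.
#' @export
segment_sweeps <- function(cv) {
  stopifnot(inherits(cv, "cyclic_voltammogram"))
  rev_idx <- .reversal_indices(cv$potential, cv$tol)
  bounds <- c(0L, rev_idx, length(cv$potential))
  segs <- vector("list", length(bounds) - 1L)
  for (k in seq_along(segs)) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    pot <- cv$potential[idx]
    direction <- if (pot[length(pot)] < pot[1L]) "cathodic" else "anodic"
    segs[[k]] <- structure(
      list(potential = pot, current = cv$current[idx], direction = direction,
           indices = idx, scan_rate = cv$scan_rate,
           temperature = cv$temperature),
      class = "cv_segment")
  }
  segs
}

#' Chronoamperogram container
#'
#' Current versus time at a fixed applied potential; the time integral of
#' the magnitude of the current is the total passed charge.
#'
#' @param time numeric vector of seconds, strictly increasing, starting at
#'   or after 0.
#' @param current numeric vector of amperes (cathodic negative).
#' @param applied_potential applied potential in volts vs Ag/AgCl.
#' @param duration measurement duration in seconds (default: last time
#'   point; the regeneration runs analysed here use 1800 s).
#' @return An object of class `chronoamperogram`.
#' @export
chronoamperogram <- function(time, current, applied_potential = NA_real_,
                             duration = NULL) {
  time <- as.numeric(time); current <- as.numeric(current)
  if (length(time) != length(current)) {
    .nadhreg_error("time and current must have equal length",
                   "nadhreg_format_error")
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    .nadhreg_error("time must be strictly increasing", "nadhreg_format_error")
  }
  if (length(time) && time[1] < 0) {
    .nadhreg_error("time must start at or after 0", "nadhreg_format_error")
  }
  if (is.null(duration)) duration <- if (length(time)) max(time) else 0
  structure(list(time = time, current = current,
                 applied_potential = applied_potential, duration = duration),
            class = "chronoamperogram")
}

#' @export
print.chronoamperogram <- function(x, ...) {
  cat(sprintf("<chronoamperogram> %d points over %g s at %g V\n",
              length(x$time), x$duration, x$applied_potential))
  invisible(x)
}

#' Impedance spectrum container
#'
#' @param frequency numeric vector of hertz, strictly monotonic, all > 0.
#' @param z complex impedances (ohm), same length as `frequency`.
#' @param bias_potential DC bias potential in volts vs Ag/AgCl.
#' @param electrode_area electrode area in cm^2.
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequency, z, bias_potential = NA_real_,
                               electrode_area = NA_real_) {
  frequency <- as.numeric(frequency)
  z <- as.complex(z)
  if (length(frequency) != length(z)) {
    .nadhreg_error("frequency and z must have equal length",
                   "nadhreg_format_error")
  }
  if (any(frequency <= 0)) {
    .nadhreg_error("frequencies must be positive", "nadhreg_domain_error")
  }
  d <- diff(frequency)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    .nadhreg_error("frequency must be strictly monotonic",
                   "nadhreg_format_error")
  }
  structure(list(frequency = frequency, z = z,
                 bias_potential = bias_potential,
                 electrode_area = electrode_area),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("<impedance_spectrum> %d frequencies %g..%g Hz, bias %g V\n",
              length(x$frequency), min(x$frequency), max(x$frequency),
              x$bias_potential))
  invisible(x)
}

#' Read a delimited potentiostat / impedance export
#'
#' Reads a comma- or tab-delimited table (auto-detected; header row
#' required, decimal point only) and maps named columns onto one of the
#' package's containers.  Units are converted to V/A/s/Hz/ohm according to
#' the `units` declaration.
#'
#' @param source path to a delimited text file, or a connection.
#' @param kind `"cv"`, `"chrono"` or `"eis"`.
#' @param column_map named character vector mapping the container fields to
#'   column names in the file: `c(potential=, current=)` for `"cv"`,
#'   `c(time=, current=)` for `"chrono"`,
#'   `c(frequency=, z_re=, z_im=)` for `"eis"`.
#' @param units optional named character vector (same names as
#'   `column_map`) with units among V, mV, A, mA, uA, s, ms, Hz, kHz, ohm,
#'   kohm; unmapped fields are assumed already in SI (V, A, s, Hz, ohm).
#' @param ... further arguments passed to the container constructor
#'   (e.g. `scan_rate` for `"cv"`, `applied_potential` for `"chrono"`).
#' @return A [cyclic_voltammogram()], [chronoamperogram()] or
#'   [impedance_spectrum()].
#' @export
read_electrochem_table <- function(source, kind = c("cv", "chrono", "eis"),
                                   column_map, units = NULL, ...) {
  kind <- match.arg(kind)
  required <- switch(kind,
    cv = c("potential", "current"),
    chrono = c("time", "current"),
    eis = c("frequency", "z_re", "z_im"))
  missing_fields <- setdiff(required, names(column_map))
  if (length(missing_fields)) {
    .nadhreg_error(sprintf("column map lacks field(s): %s",
                           paste(missing_fields, collapse = ", ")),
                   "nadhreg_format_error")
  }
  first <- readLines(source, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  tab <- utils::read.table(source, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  cols <- lapply(required, function(field) {
    cn <- column_map[[field]]
    if (!cn %in% names(tab)) {
      .nadhreg_error(sprintf("column '%s' (field '%s') not found in table",
                             cn, field), "nadhreg_format_error")
    }
    raw <- tab[[cn]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & nzchar(raw))
    if (length(bad)) {
      .nadhreg_error(sprintf("non-numeric value '%s' in column '%s', row %d",
                             raw[bad[1]], cn, bad[1]), "nadhreg_parse_error")
    }
    .apply_unit(val, if (!is.null(units)) units[[field]] else NULL)
  })
  names(cols) <- required
  switch(kind,
    cv = cyclic_voltammogram(cols$potential, cols$current, ...),
    chrono = chronoamperogram(cols$time, cols$current, ...),
    eis = impedance_spectrum(cols$frequency,
                             complex(real = cols$z_re,
                                     imaginary = cols$z_im), ...))
}

#' Write a container back to delimited text
#'
#' Writes the numeric columns of a voltammogram, chronoamperogram or
#' impedance spectrum as a CSV with canonical headers (`potential,current`;
#' `time,current`; `frequency,z_re,z_im`).  Values keep 15 significant
#' digits, so a write/read round trip is lossless to well below 1e-12
#' relative.
#'
#' @param x one of the three containers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_electrochem_table <- function(x, path) {
  df <- if (inherits(x, "cyclic_voltammogram")) {
    data.frame(potential = x$potential, current = x$current)
  } else if (inherits(x, "chronoamperogram")) {
    data.frame(time = x$time, current = x$current)
  } else if (inherits(x, "impedance_spectrum")) {
    data.frame(frequency = x$frequency, z_re = Re(x$z), z_im = Im(x$z))
  } else {
    .nadhreg_error("unsupported object", "nadhreg_format_error")
  }
  df[] <- lapply(df, function(col) format(col, digits = 15, trim = TRUE,
                                          scientific = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate voltammograms on a common potential grid
#'
#' Replicates recorded with the same waveform and scan rate are segmented,
#' each segment's currents are interpolated onto a common potential grid,
#' and the pointwise mean and sample (n-1) standard deviation are returned
#' (the shaded-band summary used when at least 3 repeat CVs are recorded).
#'
#' @param cvs list of [cyclic_voltammogram()] objects (>= 2) at identical
#'   scan rate and vertices.
#' @param rel_tol relative tolerance for scan-rate / vertex agreement.
#' @return An object of class `replicate_summary`: a data frame with
#'   columns `segment`, `potential`, `current_mean`, `current_sd`, plus
#'   attributes `n_replicates` and `scan_rate`.
#' @export
aggregate_replicates <- function(cvs, rel_tol = 1e-6) {
  if (!is.list(cvs) || length(cvs) < 2) {
    .nadhreg_error("need at least 2 replicates", "nadhreg_insufficient_replicates")
  }
  stopifnot(all(vapply(cvs, inherits, TRUE, "cyclic_voltammogram")))
  nu <- vapply(cvs, `[[`, numeric(1), "scan_rate")
  if (diff(range(nu)) > rel_tol * max(nu)) {
    .nadhreg_error("replicates have mismatched scan rates",
                   "nadhreg_incompatible")
  }
  seglists <- lapply(cvs, segment_sweeps)
  nseg <- lengths(seglists)
  if (length(unique(nseg)) != 1) {
    .nadhreg_error("replicates have different numbers of sweep segments",
                   "nadhreg_incompatible")
  }
  v1 <- cvs[[1]]$vertices
  for (cv in cvs[-1]) {
    if (length(cv$vertices) != length(v1) ||
        any(abs(cv$vertices - v1) > cvs[[1]]$tol + rel_tol * max(abs(v1)))) {
      .nadhreg_error("replicates have mismatched waveform vertices",
                     "nadhreg_incompatible")
    }
  }
  out <- NULL
  for (k in seq_len(nseg[1])) {
    ref <- seglists[[1]][[k]]
    grid <- seq(ref$potential[1], ref$potential[length(ref$potential)],
                length.out = length(ref$potential))
    mat <- vapply(seglists, function(sl) {
      s <- sl[[k]]
      stats::approx(s$potential, s$current, xout = grid, rule = 2,
                    ties = mean)$y
    }, numeric(length(grid)))
    out <- rbind(out, data.frame(
      segment = k, potential = grid,
      current_mean = rowMeans(mat),
      current_sd = apply(mat, 1, stats::sd)))
  }
  structure(out, n_replicates = length(cvs), scan_rate = nu[1],
            class = c("replicate_summary", "data.frame"))
}
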