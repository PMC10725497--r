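# Peak detection and Nicholson-Shain peak-shift kinetics for totally
# irreversible electron transfer.  For such a reaction the cathodic peak
# potential moves linearly with log10(scan rate); the slope carries the
# transfer-coefficient product alpha*n via
#   dE_p / dlog10(nu) = -2.303 * R * T / (2 * alpha * n * F).

.moving_average <- function(y, window) {
  if (window <= 1) return(y)
  k <- rep(1 / window, window)
  sm <- stats::filter(y, k, sides = 2)
  sm <- as.numeric(sm)
  # pad the filter's NA edges with the raw signal
  na <- is.na(sm)
  sm[na] <- y[na]
  sm
}

#' Detect faradaic peaks in a monotonic sweep segment
#'
#' Fits a straight baseline to a pre-peak "foot" region, subtracts it, and
#' locates the extremum of the (smoothed) corrected current inside a
#' potential search window.  Smoothing is used only to localise the
#' extremum; the reported peak current is the unsmoothed baseline-corrected
#' current.  Equal-current plateaus report the plateau midpoint.
#'
#' @param segment a sweep segment from [segment_sweeps()], or any list with
#'   numeric `potential` and `current` of equal length.
#' @param direction `"cathodic"` (minimum sought) or `"anodic"` (maximum);
#'   defaults to the segment's own direction tag.
#' @param smooth_window centred moving-average width in points (odd,
#'   default 5).
#' @param min_prominence minimum baseline-corrected peak magnitude in
#'   amperes for a peak to be reported (default 0).
#' @param search_window optional numeric length-2 potential interval (V)
#'   restricting the peak search.
#' @param foot_frac fraction of the sweep preceding the search window used
#'   for the linear baseline fit (default 0.3).
#' @return A list of `peak` objects sorted by decreasing `|i_p|`; each has
#'   `E_p` (V), `i_p` (A, signed, baseline-corrected), `direction`,
#'   `baseline` (slope, intercept), `prominence` (A) and `index`.
#' @export
detect_peaks <- function(segment, direction = NULL, smooth_window = 5,
                         min_prominence = 0, search_window = NULL,
                         foot_frac = 0.3) {
  pot <- segment$potential; cur <- segment$current
  if (is.null(direction)) direction <- segment$direction
  direction <- match.arg(direction, c("cathodic", "anodic"))
  n <- length(pot)
  if (n < max(5, smooth_window)) {
    .nadhreg_error("segment too short for peak detection",
                   "nadhreg_insufficient_data")
  }
  if (smooth_window %% 2 == 0) {
    .nadhreg_error("smooth_window must be odd", "nadhreg_domain_error")
  }
  if (!is.null(search_window)) {
    search_window <- sort(as.numeric(search_window))
    in_win <- pot >= search_window[1] & pot <= search_window[2]
    if (!any(in_win)) {
      .nadhreg_error("search window lies outside the segment's potential range",
                     "nadhreg_window_error")
    }
  } else {
    in_win <- rep(TRUE, n)
  }
  win_idx <- which(in_win)
  # baseline: straight line over the foot of the sweep preceding the window
  pre <- seq_len(max(min(win_idx) - 1L, 0L))
  foot <- if (length(pre) >= 2) {
    pre[pre > (1 - foot_frac) * length(pre)]
  } else {
    seq_len(max(2L, ceiling(foot_frac * n)))
  }
  if (length(foot) < 2) foot <- 1:2
  bl_fit <- stats::lm.fit(cbind(1, pot[foot]), cur[foot])
  bl_coef <- bl_fit$coefficients
  corrected <- cur - (bl_coef[1] + bl_coef[2] * pot)
  sm <- .moving_average(corrected, smooth_window)
  sgn <- if (direction == "cathodic") -1 else 1
  w <- sgn * sm                     # maxima of w are peaks of interest
  # floor below which a "peak" is numerical noise on a featureless trace
  prom_floor <- max(min_prominence, 1e-12 * max(abs(cur), 1e-300))
  peaks <- list()
  i <- 2L
  while (i <= n - 1L) {
    if (w[i] >= w[i - 1L]) {
      j <- i
      while (j < n && w[j + 1L] == w[i]) j <- j + 1L   # plateau
      if (j < n && w[i] >= w[j + 1L] && (w[i] > w[i - 1L] || w[i] > w[j + 1L])) {
        mid <- (i + j) %/% 2L
        if (in_win[mid]) {
          ip <- corrected[mid]
          prom <- abs(ip)
          if (prom >= prom_floor && sgn * ip > 0) {
            peaks[[length(peaks) + 1L]] <- structure(
              list(E_p = pot[mid], i_p = ip, direction = direction,
                   baseline = c(intercept = unname(bl_coef[1]),
                                slope = unname(bl_coef[2])),
                   prominence = prom, index = mid),
              class = "peak")
          }
        }
        i <- j + 1L
        next
      }
      i <- j
    }
    i <- i + 1L
  }
  peaks[order(vapply(peaks, function(p) -abs(p$i_p), numeric(1)))]
}

#' @export
print.peak <- function(x, ...) {
  cat(sprintf("<peak> %s, E_p = %.4f V, i_p = %.3e A\n",
              x$direction, x$E_p, x$i_p))
  invisible(x)
}

#' Transfer-coefficient product from the peak-shift slope
#'
#' Ordinary least-squares regression of peak potential on log10(scan rate)
#' for an irreversible electron transfer; the transfer-coefficient product
#' is recovered as `alpha*n = 2.303*R*T / (2*F*|slope|)`.
#'
#' @param points a data frame (or list) with numeric `nu` (scan rates, V/s)
#'   and `E_p` (peak potentials, V).
#' @param temperature absolute temperature in kelvin (default 293).
#' @return An object of class `kinetics_fit` with `slope` (V/decade),
#'   `intercept` (V), `alpha_n`, `temperature`, `rse` (residual standard
#'   error), `n_points` and a `warnings` character vector (a direction
#'   warning is attached when the slope of cathodic data is positive).
#' @export
peak_shift_fit <- function(points, temperature = 293) {
  nu <- as.numeric(points$nu); ep <- as.numeric(points$E_p)
  if (length(nu) != length(ep)) {
    .nadhreg_error("nu and E_p must have equal length", "nadhreg_format_error")
  }
  if (any(nu <= 0)) {
    .nadhreg_error("scan rates must be positive", "nadhreg_domain_error")
  }
  if (length(unique(nu)) < 2) {
    .nadhreg_error("need at least 2 distinct scan rates",
                   "nadhreg_insufficient_data")
  }
  x <- log10(nu)
  fit <- stats::lm(ep ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope == 0) {
    .nadhreg_error("zero peak-shift slope: kinetics not identifiable",
                   "nadhreg_nonidentifiable")
  }
  warn <- character(0)
  if (slope > 0) {
    warn <- "positive peak-shift slope: not consistent with a cathodic irreversible shift"
  }
  rse <- if (length(nu) > 2)
    sqrt(sum(stats::residuals(fit)^2) / (length(nu) - 2)) else NA_real_
  structure(
    list(slope = slope, intercept = intercept,
         alpha_n = peak_shift_constant(temperature) / abs(slope),
         temperature = temperature, rse = rse, n_points = length(nu),
         warnings = warn),
    class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetics_fit> slope = %.1f mV/decade (n = %d, T = %g K)\n  alpha*n = %.3f\n",
    1000 * x$slope, x$n_points, x$temperature, x$alpha_n))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' Two-point transfer-coefficient product
#'
#' Closed-form `alpha*n` from two (scan rate, peak potential) pairs:
#' `alpha*n = -R*T*ln(nu2/nu1) / (2*F*(E_p2 - E_p1))`.  Symmetric under
#' swapping the two points.
#'
#' @param E_p1,E_p2 peak potentials (V).
#' @param nu1,nu2 scan rates (V/s), distinct and positive.
#' @param temperature absolute temperature (K).
#' @return The dimensionless transfer-coefficient product.
#' @export
two_point_alpha_n <- function(E_p1, nu1, E_p2, nu2, temperature = 293) {
  if (nu1 <= 0 || nu2 <= 0) {
    .nadhreg_error("scan rates must be positive", "nadhreg_domain_error")
  }
  if (nu1 == nu2) {
    .nadhreg_error("identical scan rates: alpha*n not identifiable",
                   "nadhreg_nonidentifiable")
  }
  if (E_p1 == E_p2) {
    .nadhreg_error("identical peak potentials: alpha*n not identifiable",
                   "nadhreg_nonidentifiable")
  }
  -GAS_CONSTANT * temperature * log(nu2 / nu1) /
    (2 * FARADAY * (E_p2 - E_p1))
}

#' Diffusion-control diagnostics: peak current versus sqrt(scan rate)
#'
#' For a diffusion-controlled peak the peak current grows with the square
#' root of the scan rate (Randles-Sevcik scaling); a straight fit through
#' the origin with R^2 near 1 flags diffusion control.
#'
#' @param points a data frame (or list) with numeric `nu` (V/s) and `i_p`
#'   (A).
#' @return A list with `slope` (A per sqrt(V/s)), `intercept` (A),
#'   `r_squared`, `n_points` and `diffusion_controlled` (logical: R^2 >
#'   0.99 and intercept below 5% of the fitted range).
#' @export
scan_rate_current_fit <- function(points) {
  nu <- as.numeric(points$nu); ip <- as.numeric(points$i_p)
  if (any(nu <= 0)) {
    .nadhreg_error("scan rates must be positive", "nadhreg_domain_error")
  }
  if (length(unique(nu)) < 2) {
    .nadhreg_error("need at least 2 distinct scan rates",
                   "nadhreg_insufficient_data")
  }
  x <- sqrt(nu)
  fit <- stats::lm(ip ~ x)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  sst <- sum((ip - mean(ip))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  list(slope = slope, intercept = intercept,
       r_squared = r2, n_points = length(nu),
       diffusion_controlled = isTRUE(r2 > 0.99) &&
         abs(intercept) < 0.05 * max(abs(ip)))
}
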