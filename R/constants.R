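#' Physical constants
#'
#' Fixed named constants used throughout the voltammetric kinetics and
#' charge-balance computations.
#'
#' @format
#' * `GAS_CONSTANT` — universal gas constant R, 8.314 J mol^-1 K^-1.
#' * `FARADAY` — Faraday constant F, 96485 C mol^-1.
#' @name constants
NULL

#' @rdname constants
#' @export
GAS_CONSTANT <- 8.314

#' @rdname constants
#' @export
FARADAY <- 96485

#' Slope constant of the decade-logarithm peak-shift law
#'
#' For a totally irreversible one-step reduction the cathodic peak potential
#' shifts linearly with the decade logarithm of the scan rate; the
#' proportionality constant is `ln(10) * R * T / (2 * F)` volts per decade
#' (the decade-log factor 2.303...), so that
#' `alpha*n = peak_shift_constant(T) / |slope|`.  At 293 K this evaluates
#' to 0.029 V/decade (three decimals).  The exact `ln(10)` is used rather
#' than the rounded 2.303 so the decade-log slope route and the
#' natural-log two-point route give identical `alpha*n`.
#'
#' @param temperature absolute temperature in kelvin.
#' @return Volts per decade of scan rate (positive).
#' @examples
#' peak_shift_constant(293)   # 0.02907...
#' @export
peak_shift_constant <- function(temperature = 293) {
  stopifnot(is.numeric(temperature), temperature > 0)
  log(10) * GAS_CONSTANT * temperature / (2 * FARADAY)
}
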