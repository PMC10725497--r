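# Shared fixture builders; all data generated in code.

# ground-truth parameter sets for the four circuit presets, with magnitudes
# typical of glassy-carbon spectra
eec_true_params <- list(
  EEC_A = c(Rs = 30, Rp = 1500, Y0 = 2e-5, n = 0.9),
  EEC_B = c(Rs = 30, Rp = 800, Y0 = 2e-5, n = 0.9, Yw = 2e-3),
  EEC_C = c(Rs = 30, R1 = 400, Y01 = 1e-5, n1 = 0.92,
            R2 = 1200, Y02 = 8e-5, n2 = 0.85, Yw = 1.5e-3),
  EEC_D = c(Rs = 30, R1 = 400, Y01 = 1e-5, n1 = 0.92,
            R2 = 1200, Y02 = 8e-5, n2 = 0.85))

# triangular ramp with a gaussian cathodic peak on a linear baseline
gaussian_peak_segment <- function(center = -1.10, amplitude = -2e-5,
                                  width = 0.05, slope = 1e-6,
                                  intercept = -2e-6, dE = 0.002) {
  pot <- seq(0, -1.8, by = -dE)
  cur <- intercept + slope * pot + amplitude * exp(-(pot - center)^2 /
                                                    (2 * width^2))
  structure(list(potential = pot, current = cur, direction = "cathodic"),
            class = "cv_segment")
}

# simple monotonic-ramp voltammogram with constant current
ramp_cv <- function(current = -1e-6, scan_rate = 0.1) {
  pot <- seq(0, -1, by = -0.01)
  cyclic_voltammogram(pot, rep(current, length(pot)), scan_rate)
}
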