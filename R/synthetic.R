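# Seeded synthetic-data generators with serialized ground truth: a
# finite-difference simulator of totally irreversible voltammetry (with an
# optional first-order catalytic regeneration term), equivalent-circuit
# impedance spectra, chronoamperograms, and Beer-Lambert assay extinction
# sets.  Every generator is deterministic given (configuration, seed), and
# each returns the generated dataset together with a `synthetic_truth`
# record of the parameters that produced it.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

.synthetic_truth <- function(...) {
  structure(list(...), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Kinetic ground truth for the voltammetry simulator
#'
#' Parameter record for a one-step, totally irreversible reduction.  The
#' diffusion coefficient and standard rate constant are generator
#' placeholders (no measured values exist for them in this system); they
#' are recorded in every truth sidecar.
#'
#' @param alpha charge-transfer coefficient (dimensionless).
#' @param n_electrons number of transferred electrons.
#' @param k0 standard heterogeneous rate constant in cm/s.
#' @param E0_prime formal potential in V vs Ag/AgCl.
#' @param D diffusion coefficient in cm^2/s.
#' @param c_bulk bulk analyte concentration in mM.
#' @param electrode_area electrode area in cm^2 (default: 2 mm rod).
#' @param temperature absolute temperature in K.
#' @return A `synthetic_truth` record; `alpha_n = alpha * n_electrons` is
#'   the product the peak-shift analysis recovers.
#' @export
cv_truth <- function(alpha = 0.49, n_electrons = 1, k0 = 1e-4,
                     E0_prime = -0.88, D = 5e-6, c_bulk = 5,
                     electrode_area = pi * 0.1^2, temperature = 293) {
  stopifnot(alpha > 0, n_electrons > 0, D > 0, c_bulk > 0,
            electrode_area > 0, temperature > 0)
  if (k0 <= 0) {
    .nadhreg_error("k0 must be positive", "nadhreg_domain_error")
  }
  .synthetic_truth(alpha = alpha, n_electrons = n_electrons,
                   alpha_n = alpha * n_electrons, k0 = k0,
                   E0_prime = E0_prime, D = D, c_bulk = c_bulk,
                   electrode_area = electrode_area,
                   temperature = temperature)
}

# triangular potential programme sampled every dE volts
.waveform <- function(vertices, dE) {
  pot <- vertices[1]
  for (k in seq_len(length(vertices) - 1L)) {
    from <- vertices[k]; to <- vertices[k + 1L]
    nstep <- max(1L, round(abs(to - from) / dE))
    pot <- c(pot, from + (to - from) * seq_len(nstep) / nstep)
  }
  pot
}

# 1-D semi-infinite diffusion to a planar electrode with a totally
# irreversible Butler-Volmer flux boundary, on an expanding spatial grid.
# Optionally tracks the reduced product B with first-order homogeneous
# regeneration B -> A at rate k_cat (EC' caricature).  Implicit (backward
# Euler) stepping by default; explicit stepping available with a checked
# stability bound.
.cv_engine <- function(truth, scan_rate, vertices, dE, h0, beta_grid,
                       box_factor, method, k_cat) {
  an <- truth$alpha_n
  R <- GAS_CONSTANT; Fc <- FARADAY
  temp <- truth$temperature
  pot <- .waveform(vertices, dE)
  nstep <- length(pot) - 1L
  dt <- dE / scan_rate
  t_total <- nstep * dt
  a_rate <- an * Fc * scan_rate / (R * temp)           # 1/s
  x_char <- sqrt(truth$D / a_rate)                     # reaction layer, cm
  h1 <- h0 * x_char
  x_need <- box_factor * sqrt(truth$D * t_total)
  nh <- ceiling(log(1 + (beta_grid - 1) * x_need / h1) / log(beta_grid))
  h <- h1 * beta_grid^(0:(nh - 1L))
  nn <- length(h)                                      # nodes 1..nn, node 0 at surface
  # interior nodes 1..nn-1; node nn is the Dirichlet far boundary
  hl <- h[1:(nn - 1L)]; hr <- h[2:nn]
  aW <- 2 * truth$D / (hl * (hl + hr))
  aE <- 2 * truth$D / (hr * (hl + hr))
  if (method == "explicit") {
    dt_max <- 1 / max(aW + aE)
    if (dt > dt_max) {
      .nadhreg_error(sprintf(
        "explicit stepping unstable: dt = %.3g s exceeds the diffusion bound dt <= 1/max(2D/(h_l*h_r)) = %.3g s; reduce dE or coarsen the grid",
        dt, dt_max), "nadhreg_stability_error")
    }
  }
  cb <- truth$c_bulk * 1e-6                            # mM -> mol/cm^3
  ni <- nn - 1L
  cA <- rep(cb, ni); cB <- rep(0, ni)
  kf_all <- truth$k0 *
    exp(-an * Fc * (pot - truth$E0_prime) / (R * temp))
  current <- numeric(nstep + 1L)
  g0 <- 1 / (1 + kf_all[1] * h1 / truth$D)
  current[1] <- -truth$n_electrons * Fc * truth$electrode_area *
    kf_all[1] * g0 * cA[1]
  track_b <- k_cat > 0
  decay <- exp(-k_cat * dt)
  diagA <- 1 + dt * (aW + aE)
  low <- -dt * aW; up <- -dt * aE
  cp <- numeric(ni); dp <- numeric(ni)
  for (s in seq_len(nstep)) {
    kf <- kf_all[s + 1L]
    if (track_b) {                                      # exact reaction split
      dB <- cB * (1 - decay)
      cA <- cA + dB
      cB <- cB - dB
    }
    g <- 1 / (1 + kf * h1 / truth$D)
    if (method == "implicit") {
      # Thomas solve for A: rows 1..ni, surface BC folded into row 1
      b1 <- diagA[1] + low[1] * g
      d1 <- cA[1]
      cp[1] <- up[1] / b1
      dp[1] <- d1 / b1
      for (j in 2:ni) {
        rhs <- cA[j] + if (j == ni) -up[ni] * cb else 0
        m <- diagA[j] - low[j] * cp[j - 1L]
        cp[j] <- up[j] / m
        dp[j] <- (rhs - low[j] * dp[j - 1L]) / m
      }
      cA[ni] <- dp[ni]
      for (j in (ni - 1L):1L) cA[j] <- dp[j] - cp[j] * cA[j + 1L]
      c0A <- g * cA[1]
      if (track_b) {
        # product influx: D * (cB1 - cB0)/h1 = -kf * c0A
        src <- kf * c0A * h1 / truth$D
        b1 <- diagA[1] + low[1]                         # ghost cB0 = cB1 + src
        d1 <- cB[1] - low[1] * src
        cp[1] <- up[1] / b1
        dp[1] <- d1 / b1
        for (j in 2:ni) {
          m <- diagA[j] - low[j] * cp[j - 1L]
          cp[j] <- up[j] / m
          dp[j] <- (cB[j] - low[j] * dp[j - 1L]) / m
        }
        cB[ni] <- dp[ni]
        for (j in (ni - 1L):1L) cB[j] <- dp[j] - cp[j] * cB[j + 1L]
      }
    } else {                                            # explicit
      c0A <- g * cA[1]
      lapA <- aW * c(c0A, cA[-ni]) - (aW + aE) * cA +
        aE * c(cA[-1], cb)
      if (track_b) {
        c0B <- cB[1] + kf * c0A * h1 / truth$D
        lapB <- aW * c(c0B, cB[-ni]) - (aW + aE) * cB +
          aE * c(cB[-1], 0)
        cB <- cB + dt * lapB
      }
      cA <- cA + dt * lapA
      c0A <- g * cA[1]
    }
    current[s + 1L] <- -truth$n_electrons * Fc * truth$electrode_area *
      kf * c0A
  }
  list(potential = pot, current = current)
}

#' Simulate a cyclic voltammogram of a totally irreversible reduction
#'
#' Solves 1-D semi-infinite planar diffusion with the irreversible
#' Butler-Volmer flux boundary
#' `i = -n F A k0 c(0,t) exp(-alpha n F (E - E0')/(R T))`
#' over a triangular potential programme, by backward-Euler stepping on an
#' exponentially expanding spatial grid (first cell a fraction `h0` of the
#' kinetic reaction layer `sqrt(D R T/(alpha n F nu))`, simulation box
#' `box_factor * sqrt(D t_total)`).  The cathodic peak of the result obeys
#' the Nicholson-Shain peak-shift law, so the simulator serves as a forward
#' model for the `alpha*n` analysis.
#'
#' @param truth a [cv_truth()] record.
#' @param scan_rate scan rate in V/s.
#' @param vertices waveform vertices in V (default `0 -> -1.8 -> 1 -> 0`).
#' @param dE potential step in V (default 1 mV).
#' @param h0 first grid cell as a fraction of the reaction layer.
#' @param beta_grid grid expansion factor (> 1).
#' @param box_factor simulation box in units of `sqrt(D t_total)`.
#' @param method `"implicit"` (unconditionally stable, default) or
#'   `"explicit"` (errors when the diffusion stability bound is violated).
#' @param noise proportional Gaussian current noise level (default 0).
#' @param seed seed for the noise (required when `noise > 0`).
#' @return A list with `cv` (a [cyclic_voltammogram()]) and `truth` (the
#'   input record extended with the grid controls and seed).
#' @export
simulate_irreversible_cv <- function(truth = cv_truth(), scan_rate = 0.1,
                                     vertices = c(0, -1.8, 1, 0),
                                     dE = 1e-3, h0 = 0.05,
                                     beta_grid = 1.15, box_factor = 6,
                                     method = c("implicit", "explicit"),
                                     noise = 0, seed = NULL) {
  method <- match.arg(method)
  stopifnot(scan_rate > 0, dE > 0, h0 > 0, beta_grid > 1, box_factor > 0,
            noise >= 0)
  res <- .cv_engine(truth, scan_rate, vertices, dE, h0, beta_grid,
                    box_factor, method, k_cat = 0)
  cur <- res$current
  if (noise > 0) {
    cur <- .with_seed(seed,
      cur * (1 + noise * stats::rnorm(length(cur))))
  }
  cv <- cyclic_voltammogram(res$potential, cur, scan_rate,
                            vertices = vertices,
                            temperature = truth$temperature,
                            electrode_area = truth$electrode_area)
  truth_out <- truth
  truth_out$scan_rate <- scan_rate
  truth_out$grid <- list(dE = dE, h0 = h0, beta_grid = beta_grid,
                         box_factor = box_factor, method = method)
  truth_out$noise <- noise
  truth_out$seed <- seed
  list(cv = cv, truth = truth_out)
}

#' Simulate a catalytically amplified voltammogram (EC' caricature)
#'
#' Adds a first-order homogeneous regeneration of the oxidised analyte
#' from the reduced product (rate `k_cat`, 1/s) to the diffusion problem of
#' [simulate_irreversible_cv()].  This is a deliberate caricature of the
#' mediated catalytic cycle -- a single pseudo-first-order step, not a
#' mechanistic multi-step model.  With `k_cat = 0` the output is identical
#' to the uncatalysed simulator; for `k_cat > 0` the cathodic peak current
#' is strictly amplified.
#'
#' @inheritParams simulate_irreversible_cv
#' @param k_cat pseudo-first-order regeneration rate constant (1/s, >= 0).
#' @return As [simulate_irreversible_cv()].
#' @export
simulate_catalytic_cv <- function(truth = cv_truth(), k_cat = 0,
                                  scan_rate = 0.1,
                                  vertices = c(0, -1.8, 1, 0),
                                  dE = 1e-3, h0 = 0.05, beta_grid = 1.15,
                                  box_factor = 6,
                                  method = c("implicit", "explicit"),
                                  noise = 0, seed = NULL) {
  method <- match.arg(method)
  if (k_cat < 0) {
    .nadhreg_error("k_cat must be non-negative", "nadhreg_domain_error")
  }
  res <- .cv_engine(truth, scan_rate, vertices, dE, h0, beta_grid,
                    box_factor, method, k_cat = k_cat)
  cur <- res$current
  if (noise > 0) {
    cur <- .with_seed(seed,
      cur * (1 + noise * stats::rnorm(length(cur))))
  }
  cv <- cyclic_voltammogram(res$potential, cur, scan_rate,
                            vertices = vertices,
                            temperature = truth$temperature,
                            electrode_area = truth$electrode_area)
  truth_out <- truth
  truth_out$k_cat <- k_cat
  truth_out$scan_rate <- scan_rate
  truth_out$seed <- seed
  list(cv = cv, truth = truth_out)
}

#' Simulate a noisy impedance spectrum from a circuit preset
#'
#' Evaluates [impedance_of()] and perturbs real and imaginary parts with
#' independent proportional Gaussian noise.
#'
#' @param circuit a `circuit_model` (e.g. [eec_preset()]).
#' @param params named numeric parameter values.
#' @param frequencies frequency grid in Hz (default 61 points,
#'   0.1 Hz .. 100 kHz logarithmic).
#' @param noise relative noise scale sigma (>= 0).
#' @param seed seed controlling the noise draw.
#' @param ... passed to [impedance_of()].
#' @return A list with `spectrum` (an [impedance_spectrum()]) and `truth`.
#' @export
simulate_eis <- function(circuit, params,
                         frequencies = 10^seq(-1, 5, length.out = 61),
                         noise = 0, seed = NULL, ...) {
  stopifnot(noise >= 0)
  spec <- impedance_of(circuit, params, frequencies, ...)
  if (noise > 0) {
    spec$z <- .with_seed(seed, {
      m <- length(spec$z)
      complex(real = Re(spec$z) * (1 + noise * stats::rnorm(m)),
              imaginary = Im(spec$z) * (1 + noise * stats::rnorm(m)))
    })
  }
  list(spectrum = spec,
       truth = .synthetic_truth(preset = attr(circuit, "preset"),
                                params = unlist(params), noise = noise,
                                seed = seed))
}

#' Simulate a regeneration chronoamperogram
#'
#' `i(t) = -(i_faradaic + cap_amplitude * exp(-t / cap_tau))` plus optional
#' proportional Gaussian noise, sampled on a uniform grid.  The truth
#' record keeps the faradaic charge (`i_faradaic * duration`) separate from
#' the capacitive charge; the latter is quoted as the trapezoidal integral
#' on the sampling grid, i.e. exactly what charge integration of the
#' noiseless trace returns.
#'
#' @param i_faradaic steady faradaic current magnitude in A.
#' @param cap_amplitude initial capacitive current magnitude in A.
#' @param cap_tau capacitive time constant in s.
#' @param duration measurement duration in s (study protocol: 1800).
#' @param dt sampling interval in s.
#' @param applied_potential applied potential in V.
#' @param noise proportional Gaussian noise level.
#' @param seed seed for the noise.
#' @return A list with `trace` (a [chronoamperogram()]) and `truth`
#'   (`q_faradaic`, `q_capacitive`, `q_total` in C).
#' @export
simulate_chronoamperometry <- function(i_faradaic = 1e-3,
                                       cap_amplitude = 5e-4, cap_tau = 5,
                                       duration = 1800, dt = 1,
                                       applied_potential = -0.75,
                                       noise = 0, seed = NULL) {
  stopifnot(i_faradaic >= 0, cap_amplitude >= 0, cap_tau > 0,
            duration > 0, dt > 0, noise >= 0)
  time <- seq(0, duration, by = dt)
  cap <- cap_amplitude * exp(-time / cap_tau)
  cur <- -(i_faradaic + cap)
  if (noise > 0) {
    cur <- .with_seed(seed, cur * (1 + noise * stats::rnorm(length(cur))))
  }
  trace <- chronoamperogram(time, cur, applied_potential, duration)
  q_cap <- pracma::trapz(time, cap)
  list(trace = trace,
       truth = .synthetic_truth(i_faradaic = i_faradaic,
                                cap_amplitude = cap_amplitude,
                                cap_tau = cap_tau, duration = duration,
                                q_faradaic = i_faradaic * duration,
                                q_capacitive = q_cap,
                                q_total = i_faradaic * duration + q_cap,
                                noise = noise, seed = seed))
}

#' Simulate the assay solution set and its calibration series
#'
#' Forward Beer-Lambert model of the five-solution scheme: the diluted
#' electrolyte (A), the diluted regenerated solution (B, C), the cuvette
#' before (D) and after (E) the LDH step, each at the fixed 0.8 dilution,
#' with matching linear calibration series generated from the same
#' extinction coefficients.  Only the Rh complex absorbs at 430 nm; the
#' active and inactive NAD species absorb at 340 nm only.
#'
#' @param c_active true active 1,4-NADH concentration in mM.
#' @param c_inactive true 340 nm-absorbing inactive species pool in mM
#'   (1,2-/1,6-NADH and NAD2, expressed on the active-species extinction
#'   scale of `eps_inactive_340`).
#' @param c_rh_d,c_rh_e Rh-complex concentration (mM) in cuvettes D and E.
#' @param c_rh_pre Rh-complex concentration in the pre-regeneration
#'   electrolyte (default: same as D).
#' @param eps_active_340 extinction coefficient of 1,4-NADH at 340 nm
#'   (per mM, at the assay path length).
#' @param eps_inactive_340 mean extinction coefficient of the inactive
#'   pool at 340 nm.
#' @param eps_rh_340,eps_rh_430 Rh-complex coefficients.
#' @param cal_conc_nadh,cal_conc_rh calibration concentration series (mM).
#' @param noise proportional Gaussian noise on every extinction.
#' @param seed seed for the noise.
#' @return A list with `set` (an [assay_solution_set()]), the three fitted
#'   calibration curves (`cal_nadh_340`, `cal_rh_340`, `cal_rh_430`), and
#'   `truth` (concentrations, the implied selectivity, and the undiluted
#'   340 nm extinctions of the active and total NAD species).
#' @export
simulate_assay_set <- function(c_active = 0.2, c_inactive = 0.013,
                               c_rh_d = 0.2, c_rh_e = 0.19,
                               c_rh_pre = c_rh_d,
                               eps_active_340 = 6.3,
                               eps_inactive_340 = 5.0,
                               eps_rh_340 = 0.2, eps_rh_430 = 0.5,
                               cal_conc_nadh = seq(0, 0.25, by = 0.05),
                               cal_conc_rh = seq(0, 0.5, by = 0.1),
                               noise = 0, seed = NULL) {
  if (any(c(c_active, c_inactive, c_rh_d, c_rh_e, c_rh_pre) < 0)) {
    .nadhreg_error("concentrations must be non-negative",
                   "nadhreg_domain_error")
  }
  stopifnot(eps_active_340 >= 0, eps_inactive_340 >= 0, eps_rh_340 >= 0,
            eps_rh_430 >= 0, noise >= 0)
  dil <- .DILUTION
  ext_active <- c_active * eps_active_340
  ext_inactive <- c_inactive * eps_inactive_340
  ext340 <- c(A = dil * c_rh_pre * eps_rh_340,
              B = dil * (ext_active + ext_inactive + c_rh_pre * eps_rh_340),
              C = dil * (ext_active + ext_inactive + c_rh_d * eps_rh_340),
              D = dil * (ext_active + ext_inactive + c_rh_d * eps_rh_340),
              E = dil * (ext_inactive + c_rh_e * eps_rh_340))
  ext430 <- c(A = dil * c_rh_pre * eps_rh_430,
              B = dil * c_rh_pre * eps_rh_430,
              C = dil * c_rh_d * eps_rh_430,
              D = dil * c_rh_d * eps_rh_430,
              E = dil * c_rh_e * eps_rh_430)
  cal_ext_nadh <- cal_conc_nadh * eps_active_340
  cal_ext_rh340 <- cal_conc_rh * eps_rh_340
  cal_ext_rh430 <- cal_conc_rh * eps_rh_430
  if (noise > 0) {
    .with_seed(seed, {
      jitter <- function(x) x * (1 + noise * stats::rnorm(length(x)))
      ext340 <- jitter(ext340); ext430 <- jitter(ext430)
      cal_ext_nadh <- jitter(cal_ext_nadh)
      cal_ext_rh340 <- jitter(cal_ext_rh340)
      cal_ext_rh430 <- jitter(cal_ext_rh430)
    })
  }
  selectivity_true <-
    if (ext_active + ext_inactive > 0)
      ext_active / (ext_active + ext_inactive) else NA_real_
  list(
    set = assay_solution_set(ext340, ext430),
    cal_nadh_340 = fit_calibration(cal_conc_nadh, cal_ext_nadh,
                                   "1,4-NADH", 340),
    cal_rh_340 = fit_calibration(cal_conc_rh, cal_ext_rh340,
                                 "Rh-complex", 340),
    cal_rh_430 = fit_calibration(cal_conc_rh, cal_ext_rh430,
                                 "Rh-complex", 430),
    truth = .synthetic_truth(
      c_active = c_active, c_inactive = c_inactive,
      c_rh_d = c_rh_d, c_rh_e = c_rh_e, c_rh_pre = c_rh_pre,
      eps = c(active_340 = eps_active_340, inactive_340 = eps_inactive_340,
              rh_340 = eps_rh_340, rh_430 = eps_rh_430),
      ext_active_340 = ext_active, ext_total_340 = ext_active + ext_inactive,
      selectivity = selectivity_true, noise = noise, seed = seed))
}

#' Generate a full, internally consistent synthetic regeneration experiment
#'
#' Builds the experiment in the order of the regeneration protocol: a
#' pre-regeneration voltammogram, the 1800 s chronoamperogram, a
#' post-regeneration voltammogram, the assay solution set, and (optionally)
#' an impedance spectrum.  The configured true selectivity and Faraday
#' efficiency are built in exactly: the inactive-pool concentration is
#' chosen so the 340 nm absorbance fraction equals `selectivity`, and the
#' faradaic current is chosen so that
#' `q_theo = 2 F c_active V = eta_f * q_total` holds to machine precision
#' before noise (with `q_total` the trapezoidal charge of the noiseless
#' trace).
#'
#' @param config optional named list overriding any of: `selectivity`
#'   (0.95), `eta_f` (0.8), `c_active` mM (0.2), `volume` L (0.02), `area`
#'   cm^2 (4), `duration` s (1800), `applied_potential` V (-0.75),
#'   `scan_rate` V/s (0.1), `cap_amplitude` A (5e-4), `cap_tau` s (5),
#'   `dt` s (1), `c_rh` mM (0.25), `noise_cv`, `noise_chrono`,
#'   `noise_assay` (all 0), `cv_dE` V (2e-3), `include_eis` (FALSE),
#'   `eis_preset` ("EEC_B"), `eis_params`, `noise_eis` (0), `conditions`
#'   (named list of labels: potential, pH, buffer, mediator_mM),
#'   plus assay extinction coefficients as in [simulate_assay_set()].
#' @param seed integer seed; sub-generators derive their seeds from it, so
#'   equal (config, seed) gives identical bundles.
#' @return An object of class `nadh_bundle`: `cv_pre`, `chrono`, `cv_post`,
#'   `assay` (set + calibrations), optional `eis`, `conditions`, `config`
#'   and `truth` (with `q_theo`, `q_total`, `selectivity`, `eta_f`, the
#'   concentrations, and the seed).
#' @export
make_bundle <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    selectivity = 0.95, eta_f = 0.80, c_active = 0.2,
    volume = 0.02, area = 4, duration = 1800,
    applied_potential = -0.75, scan_rate = 0.1,
    cap_amplitude = 5e-4, cap_tau = 5, dt = 1, c_rh = 0.25,
    eps_active_340 = 6.3, eps_inactive_340 = 5.0,
    eps_rh_340 = 0.2, eps_rh_430 = 0.5,
    noise_cv = 0, noise_chrono = 0, noise_assay = 0,
    cv_dE = 2e-3, include_eis = FALSE, eis_preset = "EEC_B",
    eis_params = c(Rs = 30, Rp = 800, Y0 = 2e-5, n = 0.9, Yw = 2e-3),
    noise_eis = 0,
    conditions = list(potential = -0.75, pH = 7, buffer = "TRIS",
                      mediator_mM = 0.25)), config)
  if (cfg$selectivity <= 0 || cfg$selectivity > 1) {
    .nadhreg_error("configured selectivity must lie in (0, 1]",
                   "nadhreg_domain_error")
  }
  if (cfg$eta_f <= 0) {
    .nadhreg_error("configured eta_f must be positive",
                   "nadhreg_domain_error")
  }
  # inactive pool fixing the 340 nm absorbance fraction
  ext_active <- cfg$c_active * cfg$eps_active_340
  c_inactive <- if (cfg$eps_inactive_340 > 0)
    ext_active * (1 - cfg$selectivity) /
      (cfg$selectivity * cfg$eps_inactive_340) else 0
  # faradaic current fixing eta_f on the sampling grid
  n_mol <- cfg$c_active * 1e-3 * cfg$volume
  q_theo <- 2 * FARADAY * n_mol
  q_total <- q_theo / cfg$eta_f
  time <- seq(0, cfg$duration, by = cfg$dt)
  q_cap <- pracma::trapz(time, cfg$cap_amplitude * exp(-time / cfg$cap_tau))
  i_far <- (q_total - q_cap) / cfg$duration
  if (i_far <= 0) {
    .nadhreg_error("capacitive charge exceeds the configured total charge",
                   "nadhreg_domain_error")
  }
  chrono <- simulate_chronoamperometry(
    i_faradaic = i_far, cap_amplitude = cfg$cap_amplitude,
    cap_tau = cfg$cap_tau, duration = cfg$duration, dt = cfg$dt,
    applied_potential = cfg$applied_potential,
    noise = cfg$noise_chrono, seed = seed + 1L)
  cv_pre <- simulate_irreversible_cv(
    truth = cv_truth(c_bulk = 1), scan_rate = cfg$scan_rate,
    dE = cfg$cv_dE, noise = cfg$noise_cv, seed = seed + 2L)
  # after regeneration part of the NAD+ pool is consumed
  consumed <- cfg$c_active + c_inactive
  cv_post <- simulate_irreversible_cv(
    truth = cv_truth(c_bulk = max(1 - consumed, 0.05)),
    scan_rate = cfg$scan_rate, dE = cfg$cv_dE,
    noise = cfg$noise_cv, seed = seed + 3L)
  assay <- simulate_assay_set(
    c_active = cfg$c_active, c_inactive = c_inactive,
    c_rh_d = cfg$c_rh, c_rh_e = cfg$c_rh, c_rh_pre = cfg$c_rh,
    eps_active_340 = cfg$eps_active_340,
    eps_inactive_340 = cfg$eps_inactive_340,
    eps_rh_340 = cfg$eps_rh_340, eps_rh_430 = cfg$eps_rh_430,
    noise = cfg$noise_assay, seed = seed + 4L)
  eis <- NULL
  if (isTRUE(cfg$include_eis)) {
    eis <- simulate_eis(eec_preset(cfg$eis_preset), cfg$eis_params,
                        noise = cfg$noise_eis, seed = seed + 5L,
                        bias_potential = cfg$applied_potential)
  }
  structure(
    list(cv_pre = cv_pre$cv, chrono = chrono$trace, cv_post = cv_post$cv,
         assay = assay[c("set", "cal_nadh_340", "cal_rh_340", "cal_rh_430")],
         eis = eis, conditions = cfg$conditions, config = cfg,
         truth = .synthetic_truth(
           selectivity = cfg$selectivity, eta_f = cfg$eta_f,
           c_active = cfg$c_active, c_inactive = c_inactive,
           n_nadh_mol = n_mol, q_theo = q_theo, q_total = q_total,
           q_faradaic = chrono$truth$q_faradaic,
           q_capacitive = chrono$truth$q_capacitive,
           volume = cfg$volume, area = cfg$area,
           duration = cfg$duration, seed = seed)),
    class = "nadh_bundle")
}

#' @export
print.nadh_bundle <- function(x, ...) {
  cat(sprintf(
    "<nadh_bundle> true selectivity = %.3f, true eta_F = %.3f (seed %d)\n  %d s chronoamperogram at %g V, pre/post CVs at %g V/s%s\n",
    x$truth$selectivity, x$truth$eta_f, x$truth$seed,
    x$chrono$duration, x$config$applied_potential, x$config$scan_rate,
    if (is.null(x$eis)) "" else ", EIS spectrum"))
  invisible(x)
}
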