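# Equivalent electrical circuits (EECs) for electrochemical impedance
# spectra: a small circuit algebra over resistors, constant-phase elements
# and a semi-infinite Warburg element, a recursive forward model, complex
# nonlinear least-squares fitting in log-parameter space, and the CPE ->
# effective-capacitance conversion.
#
# Element impedances (omega = 2*pi*f):
#   Z_R   = R
#   Z_CPE = 1 / (Y0 * (j*omega)^n),  n in (0, 1]
#   Z_W   = 1 / (Yw * sqrt(j*omega))          (semi-infinite, -45 deg phase)

#' Circuit elements and composition
#'
#' Build equivalent-circuit expression trees from resistors
#' (`ckt_resistor`), constant-phase elements (`ckt_cpe`), semi-infinite
#' Warburg elements (`ckt_warburg`) and the combinators `ckt_series` /
#' `ckt_parallel`.  Leaves carry parameter *names*; numeric values are
#' supplied separately to [impedance_of()] and [fit_circuit()], so one tree
#' can be evaluated or fitted with any parameter vector.
#'
#' @param r,y0,n,yw parameter names (character scalars), e.g. `"Rs"`.
#' @param ... child circuits for the combinators.
#' @return An object of class `circuit_model`.
#' @name circuit_algebra
NULL

#' @rdname circuit_algebra
#' @export
ckt_resistor <- function(r) {
  structure(list(type = "R", params = c(R = r)), class = "circuit_model")
}

#' @rdname circuit_algebra
#' @export
ckt_cpe <- function(y0, n) {
  structure(list(type = "CPE", params = c(Y0 = y0, n = n)),
            class = "circuit_model")
}

#' @rdname circuit_algebra
#' @export
ckt_warburg <- function(yw) {
  structure(list(type = "W", params = c(Yw = yw)), class = "circuit_model")
}

#' @rdname circuit_algebra
#' @export
ckt_series <- function(...) {
  structure(list(type = "series", children = list(...)),
            class = "circuit_model")
}

#' @rdname circuit_algebra
#' @export
ckt_parallel <- function(...) {
  structure(list(type = "parallel", children = list(...)),
            class = "circuit_model")
}

circuit_param_names <- function(circuit) {
  if (circuit$type %in% c("series", "parallel")) {
    unique(unlist(lapply(circuit$children, circuit_param_names)))
  } else {
    unname(circuit$params)
  }
}

# parameter names whose value is a CPE exponent (bounded in (0, 1])
circuit_exponent_names <- function(circuit) {
  if (circuit$type %in% c("series", "parallel")) {
    unique(unlist(lapply(circuit$children, circuit_exponent_names)))
  } else if (circuit$type == "CPE") {
    unname(circuit$params[["n"]])
  } else {
    character(0)
  }
}

#' Equivalent-circuit presets
#'
#' The four circuit topologies used to fit the glassy-carbon impedance
#' spectra at increasing cathodic bias:
#'
#' * `EEC_A`: `Rs + (CPE || Rp)` — a single time constant (blank buffer at
#'   all potentials; mediator at low bias).
#' * `EEC_B`: `Rs + (CPE || (Rp + W))` — charge transfer under
#'   semi-infinite diffusion of the mediator.
#' * `EEC_C`: `Rs + (CPE1 || (R1 + (CPE2 || (R2 + W))))` — a second time
#'   constant from the forming adsorbed mediator film, still under
#'   diffusion control (the Warburg is placed in the inner mesh; the
#'   pictured circuit does not fix the branch, so this placement is an
#'   assumption of this package).
#' * `EEC_D`: `Rs + (CPE1 || (R1 + (CPE2 || R2)))` — the completed dual
#'   layer (double layer plus adsorbed film).
#'
#' @param preset one of `"EEC_A"`, `"EEC_B"`, `"EEC_C"`, `"EEC_D"`.
#' @return A `circuit_model`.  Parameter names: `Rs`, then `Rp`, `Y0`, `n`
#'   (A, B) or `R1`, `Y01`, `n1`, `R2`, `Y02`, `n2` (C, D), plus `Yw`
#'   where a Warburg is present.
#' @export
eec_preset <- function(preset = c("EEC_A", "EEC_B", "EEC_C", "EEC_D")) {
  preset <- match.arg(preset)
  ckt <- switch(preset,
    EEC_A = ckt_series(
      ckt_resistor("Rs"),
      ckt_parallel(ckt_cpe("Y0", "n"), ckt_resistor("Rp"))),
    EEC_B = ckt_series(
      ckt_resistor("Rs"),
      ckt_parallel(ckt_cpe("Y0", "n"),
                   ckt_series(ckt_resistor("Rp"), ckt_warburg("Yw")))),
    EEC_C = ckt_series(
      ckt_resistor("Rs"),
      ckt_parallel(
        ckt_cpe("Y01", "n1"),
        ckt_series(
          ckt_resistor("R1"),
          ckt_parallel(ckt_cpe("Y02", "n2"),
                       ckt_series(ckt_resistor("R2"), ckt_warburg("Yw")))))),
    EEC_D = ckt_series(
      ckt_resistor("Rs"),
      ckt_parallel(
        ckt_cpe("Y01", "n1"),
        ckt_series(
          ckt_resistor("R1"),
          ckt_parallel(ckt_cpe("Y02", "n2"), ckt_resistor("R2"))))))
  attr(ckt, "preset") <- preset
  ckt
}

#' @export
print.circuit_model <- function(x, ...) {
  fmt <- function(c) {
    switch(c$type,
      R = sprintf("R(%s)", c$params[["R"]]),
      CPE = sprintf("CPE(%s,%s)", c$params[["Y0"]], c$params[["n"]]),
      W = sprintf("W(%s)", c$params[["Yw"]]),
      series = paste0(vapply(c$children, fmt, ""), collapse = " + "),
      parallel = paste0("(", paste0(vapply(c$children, fmt, ""),
                                    collapse = " || "), ")"))
  }
  cat("<circuit_model>", fmt(x), "\n")
  invisible(x)
}

.check_circuit_params <- function(circuit, params) {
  params <- unlist(params)
  need <- circuit_param_names(circuit)
  missing_p <- setdiff(need, names(params))
  if (length(missing_p)) {
    .nadhreg_error(sprintf("missing circuit parameter(s): %s",
                           paste(missing_p, collapse = ", ")),
                   "nadhreg_parameter_error")
  }
  if (any(params[need] <= 0)) {
    .nadhreg_error("all circuit parameters must be positive",
                   "nadhreg_domain_error")
  }
  en <- circuit_exponent_names(circuit)
  if (length(en) && any(params[en] > 1)) {
    .nadhreg_error("CPE exponents must lie in (0, 1]", "nadhreg_domain_error")
  }
  invisible(TRUE)
}

.circuit_z <- function(circuit, params, jomega) {
  switch(circuit$type,
    R = rep(params[[circuit$params[["R"]]]] + 0i, length(jomega)),
    CPE = 1 / (params[[circuit$params[["Y0"]]]] *
                 jomega^params[[circuit$params[["n"]]]]),
    W = 1 / (params[[circuit$params[["Yw"]]]] * sqrt(jomega)),
    series = Reduce(`+`, lapply(circuit$children, .circuit_z,
                                params = params, jomega = jomega)),
    parallel = 1 / Reduce(`+`, lapply(circuit$children, function(ch)
      1 / .circuit_z(ch, params, jomega))))
}

#' Forward impedance of an equivalent circuit
#'
#' Evaluates the circuit tree by recursive series/parallel composition at
#' the given frequencies.
#'
#' @param circuit a `circuit_model`.
#' @param params named numeric vector of parameter values (all positive;
#'   CPE exponents in (0, 1]).
#' @param frequencies frequencies in hertz, all positive.
#' @param ... passed to [impedance_spectrum()] (e.g. `bias_potential`).
#' @return An [impedance_spectrum()].
#' @export
impedance_of <- function(circuit, params, frequencies, ...) {
  stopifnot(inherits(circuit, "circuit_model"))
  if (any(frequencies <= 0)) {
    .nadhreg_error("frequencies must be positive", "nadhreg_domain_error")
  }
  params <- unlist(params)
  .check_circuit_params(circuit, params)
  z <- .circuit_z(circuit, params, 2i * pi * frequencies)
  impedance_spectrum(frequencies, z, ...)
}

#' Effective capacitance of a CPE in parallel with a resistance
#'
#' Converts constant-phase-element parameters and the associated
#' polarization resistance into an equivalent capacitance:
#' `C_eff = (Y0 * R_p)^(1/n) / R_p * sin(n*pi/2)`.
#' For `n = 1` this reduces to `C_eff = Y0`.
#'
#' @param y0 CPE admittance coefficient (S s^n), positive.
#' @param r_p polarization resistance (ohm), positive.
#' @param n CPE exponent in (0, 1].
#' @return Capacitance in farads.
#' @examples
#' effective_capacitance(1e-5, 1e4, 0.8)   # ~5.35e-6 F
#' @export
effective_capacitance <- function(y0, r_p, n) {
  if (any(n <= 0 | n > 1)) {
    .nadhreg_error("CPE exponent n must lie in (0, 1]", "nadhreg_domain_error")
  }
  if (any(y0 <= 0) || any(r_p <= 0)) {
    .nadhreg_error("Y0 and R_p must be positive", "nadhreg_domain_error")
  }
  (y0 * r_p)^(1 / n) / r_p * sin(n * pi / 2)
}

# (CPE || R) motifs in a circuit tree: pairs a CPE leaf with the resistor
# leading the opposite branch of the same parallel node.
.cpe_r_motifs <- function(circuit) {
  motifs <- list()
  walk <- function(c) {
    if (c$type == "parallel") {
      is_cpe <- vapply(c$children, function(ch) ch$type == "CPE", TRUE)
      if (any(is_cpe)) {
        cpe <- c$children[[which(is_cpe)[1]]]
        for (ch in c$children[!is_cpe]) {
          rleaf <- if (ch$type == "R") ch
                   else if (ch$type == "series" &&
                            ch$children[[1]]$type == "R") ch$children[[1]]
                   else NULL
          if (!is.null(rleaf)) {
            motifs[[length(motifs) + 1L]] <<- c(
              Y0 = cpe$params[["Y0"]], n = cpe$params[["n"]],
              R = rleaf$params[["R"]])
          }
        }
      }
    }
    if (c$type %in% c("series", "parallel")) lapply(c$children, walk)
    invisible(NULL)
  }
  walk(circuit)
  motifs
}

# data-driven starting values for the preset parameter names
.initial_circuit_params <- function(spectrum, circuit) {
  f <- spectrum$frequency; z <- spectrum$z
  re <- Re(z); absz <- Mod(z)
  rs0 <- max(min(re), 1e-6)
  rtot <- re[which.min(f)]
  rp0 <- max(rtot - rs0, 0.05 * rs0, 1e-6)
  fmid <- f[which.min(abs(log10(f) - 3))]       # nearest to 1 kHz
  zmid <- absz[which.min(abs(log10(f) - 3))]
  y00 <- 1 / max(zmid * (2 * pi * fmid)^0.9, 1e-12)
  yw0 <- 1 / max(absz[which.min(f)] * sqrt(2 * pi * min(f)), 1e-12)
  init <- c(Rs = rs0, Rp = rp0, Y0 = y00, n = 0.9,
            R1 = 0.3 * rp0, R2 = 0.7 * rp0,
            Y01 = y00, n1 = 0.9, Y02 = 5 * y00, n2 = 0.85, Yw = yw0)
  need <- circuit_param_names(circuit)
  guess <- init[need]
  bad <- is.na(guess)
  if (any(bad)) guess[bad] <- 1       # unknown custom names
  names(guess) <- need
  guess
}

#' Fit an equivalent circuit to an impedance spectrum
#'
#' Complex nonlinear least squares: minimises the weighted sum of squared
#' real and imaginary residuals with Levenberg-Marquardt, optimising in
#' log-parameter space (logit space for CPE exponents) so positivity and
#' the exponent bound hold by construction.  Multi-start: the data-driven
#' initial guess plus seeded log-normal perturbations of it.
#'
#' @param spectrum an [impedance_spectrum()].
#' @param circuit a `circuit_model`.
#' @param init optional named numeric vector of starting values; by default
#'   a heuristic estimate from the spectrum (high-frequency intercept for
#'   `Rs`, low-frequency limit for the polarization resistances, `|Z|`
#'   near 1 kHz for the CPE).
#' @param weighting `"modulus"` (weights `1/|Z|`, i.e. squared weight
#'   `1/|Z|^2`, the default), `"unit"`, or `"proportional"` (weights
#'   `1/|Z_i|` per point, identical to modulus here; kept as an explicit
#'   option name for configuration files).
#' @param restarts number of seeded random restarts around the initial
#'   guess (default 8).
#' @param seed integer seed for the restart perturbations (default 1).
#' @return An object of class `circuit_fit`: `params` (estimates),
#'   `se` (delta-method standard errors), `residual_norm` (weighted RSS),
#'   `weighting`, `converged`, `n_freq`, `c_eff` (named vector, one entry
#'   per CPE||R motif), and the `circuit`.
#' @export
fit_circuit <- function(spectrum, circuit, init = NULL,
                        weighting = c("modulus", "unit", "proportional"),
                        restarts = 8, seed = 1) {
  stopifnot(inherits(spectrum, "impedance_spectrum"),
            inherits(circuit, "circuit_model"))
  weighting <- match.arg(weighting)
  need <- circuit_param_names(circuit)
  expo <- circuit_exponent_names(circuit)
  if (is.null(init)) init <- .initial_circuit_params(spectrum, circuit)
  .check_circuit_params(circuit, init)
  w <- switch(weighting,
              unit = rep(1, length(spectrum$z)),
              modulus = ,
              proportional = 1 / Mod(spectrum$z))
  jomega <- 2i * pi * spectrum$frequency
  to_theta <- function(p) {
    th <- log(p[need])
    th[expo] <- stats::qlogis(pmin(p[expo], 1 - 1e-9))
    th
  }
  to_params <- function(th) {
    p <- exp(th)
    p[expo] <- stats::plogis(th[expo])
    names(p) <- need
    p
  }
  resid_fn <- function(th) {
    zm <- .circuit_z(circuit, as.list(to_params(th)), jomega)
    c(w * (Re(zm) - Re(spectrum$z)), w * (Im(zm) - Im(spectrum$z)))
  }
  starts <- list(to_theta(init))
  if (restarts > 1) {
    rng_state <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    for (k in seq_len(restarts - 1)) {
      starts[[k + 1]] <- starts[[1]] +
        stats::rnorm(length(need), sd = 0.7)
    }
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, .GlobalEnv)
  }
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$deviance) best <- fit
  }
  if (is.null(best)) {
    .nadhreg_error("circuit fit failed from every start",
                   "nadhreg_fit_failure")
  }
  params <- to_params(best$par)
  # delta-method standard errors from the LM covariance in theta space
  se <- rep(NA_real_, length(need)); names(se) <- need
  cov_th <- tryCatch({
    dof <- max(2 * length(spectrum$z) - length(need), 1)
    s2 <- best$deviance / dof
    s2 * solve(best$hessian)
  }, error = function(e) NULL)
  if (!is.null(cov_th)) {
    se_th <- sqrt(pmax(diag(cov_th), 0))
    dp <- params
    dp[expo] <- params[expo] * (1 - params[expo])    # d plogis / d theta
    se <- se_th * dp
  }
  motifs <- .cpe_r_motifs(circuit)
  c_eff <- vapply(motifs, function(m)
    effective_capacitance(params[[m[["Y0"]]]], params[[m[["R"]]]],
                          params[[m[["n"]]]]), numeric(1))
  names(c_eff) <- vapply(motifs, function(m)
    paste0("C_eff(", m[["Y0"]], "||", m[["R"]], ")"), "")
  structure(
    list(params = params, se = se, residual_norm = best$deviance,
         weighting = weighting, converged = best$info %in% 1:4,
         n_freq = length(spectrum$frequency), c_eff = c_eff,
         circuit = circuit),
    class = "circuit_fit")
}

#' @export
print.circuit_fit <- function(x, ...) {
  preset <- attr(x$circuit, "preset")
  cat(sprintf("<circuit_fit>%s weighted RSS = %.4g (%s weighting)\n",
              if (is.null(preset)) "" else paste0(" ", preset),
              x$residual_norm, x$weighting))
  tab <- data.frame(estimate = signif(x$params, 5),
                    se = signif(x$se, 3))
  print(tab)
  if (length(x$c_eff)) {
    cat("effective capacitance:\n")
    print(signif(x$c_eff, 4))
  }
  invisible(x)
}

#' Rank candidate circuits for one spectrum
#'
#' Fits every candidate and ranks by a small-sample information criterion
#' (AICc computed from the weighted residual sum of squares over the 2*m
#' real/imaginary residuals, penalised by parameter count); ties break
#' toward fewer parameters.
#'
#' @param spectrum an [impedance_spectrum()].
#' @param candidates a non-empty list of `circuit_model`s.
#' @param ... passed to [fit_circuit()].
#' @return A list of `circuit_fit`s sorted best first, each with extra
#'   fields `aicc` and `n_params`; failed fits are dropped (an error is
#'   raised if all fail).
#' @export
select_model <- function(spectrum, candidates, ...) {
  if (!is.list(candidates) || length(candidates) == 0) {
    .nadhreg_error("need at least one candidate circuit",
                   "nadhreg_parameter_error")
  }
  fits <- list(); errors <- character(0)
  for (cand in candidates) {
    f <- tryCatch(fit_circuit(spectrum, cand, ...),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) { errors <- c(errors, f); next }
    k <- length(f$params)
    m <- 2 * f$n_freq
    # residuals at numerical precision are equivalent: floor the RSS so
    # parsimony, not float noise, decides between machine-exact fits
    rss <- max(f$residual_norm, m * 1e-28)
    aicc <- m * log(rss / m) + 2 * k
    if (m - k - 1 > 0) aicc <- aicc + 2 * k * (k + 1) / (m - k - 1)
    f$aicc <- aicc
    f$n_params <- k
    fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) {
    .nadhreg_error(paste("all candidate fits failed:",
                         paste(errors, collapse = "; ")),
                   "nadhreg_fit_failure")
  }
  ord <- order(vapply(fits, `[[`, numeric(1), "aicc"),
               vapply(fits, `[[`, numeric(1), "n_params"))
  fits[ord]
}
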