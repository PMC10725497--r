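# peak of the cathodic sweep of a simulated CV
sim_peak <- function(sim, window = c(-1.4, -0.8)) {
  segs <- segment_sweeps(sim$cv)
  detect_peaks(segs[[1]], search_window = window)[[1]]
}

test_that("the diffusion problem is linear in bulk concentration", {
  s1 <- simulate_irreversible_cv(cv_truth(c_bulk = 5), dE = 5e-3)
  s2 <- simulate_irreversible_cv(cv_truth(c_bulk = 10), dE = 5e-3)
  r <- sim_peak(s2)$i_p / sim_peak(s1)$i_p
  expect_lt(abs(r - 2), 0.01)          # doubling c_bulk doubles i_p
})

test_that("explicit stepping enforces its stability bound", {
  expect_error(
    simulate_irreversible_cv(scan_rate = 0.01, dE = 5e-3, h0 = 0.01,
                             method = "explicit"),
    regexp = "bound", class = "nadhreg_stability_error")
  # a stable explicit configuration agrees with the implicit solution
  si <- simulate_irreversible_cv(scan_rate = 1, dE = 1e-3, h0 = 0.5,
                                 beta_grid = 1.3)
  se <- simulate_irreversible_cv(scan_rate = 1, dE = 1e-3, h0 = 0.5,
                                 beta_grid = 1.3, method = "explicit")
  expect_lt(abs(sim_peak(se)$i_p - sim_peak(si)$i_p) /
              abs(sim_peak(si)$i_p), 0.02)
  expect_error(cv_truth(k0 = -1), class = "nadhreg_domain_error")
})

test_that("catalytic regeneration amplifies the peak monotonically", {
  base <- simulate_catalytic_cv(k_cat = 0, dE = 5e-3)
  plain <- simulate_irreversible_cv(dE = 5e-3)
  expect_identical(base$cv$current, plain$cv$current)
  # at large k the peak becomes a catalytic plateau, so compare the
  # largest cathodic current in the reduction window instead
  ip <- vapply(c(0, 2, 10, 50), function(k) {
    cv <- simulate_catalytic_cv(k_cat = k, dE = 5e-3)$cv
    sel <- cv$potential <= -0.8 & cv$potential >= -1.4
    abs(min(cv$current[sel]))
  }, numeric(1))
  expect_true(all(diff(ip) > 0))
  expect_gt(ip[2] / ip[1], 1)
  expect_error(simulate_catalytic_cv(k_cat = -1),
               class = "nadhreg_domain_error")
})

test_that("impedance generator is exact at zero noise and seed-stable", {
  ckt <- eec_preset("EEC_A")
  p <- eec_true_params$EEC_A
  clean <- simulate_eis(ckt, p)
  expect_equal(clean$spectrum$z, impedance_of(ckt, p, clean$spectrum$frequency)$z,
               tolerance = 1e-15)
  n1 <- simulate_eis(ckt, p, noise = 0.01, seed = 5)
  n2 <- simulate_eis(ckt, p, noise = 0.01, seed = 5)
  expect_identical(n1$spectrum$z, n2$spectrum$z)
  # noise magnitude check: mean absolute relative deviation ~ sigma
  madr <- mean(abs(Re(n1$spectrum$z) - Re(clean$spectrum$z)) /
                 abs(Re(clean$spectrum$z)))
  expect_gt(madr, 0.004); expect_lt(madr, 0.02)
})

test_that("chronoamperometry truth matches trapezoidal charge", {
  pure <- simulate_chronoamperometry(i_faradaic = 1e-3, cap_amplitude = 0)
  expect_equal(integrate_charge(pure$trace), 1e-3 * 1800,
               tolerance = 1e-12)
  withcap <- simulate_chronoamperometry()
  expect_equal(integrate_charge(withcap$trace), withcap$truth$q_total,
               tolerance = 1e-12)
  # tau -> 0: capacitive charge vanishes
  tiny <- simulate_chronoamperometry(cap_tau = 1e-4)
  expect_lt(tiny$truth$q_capacitive, 1e-3)
  # seeded noise perturbs the charge by well under 0.5%
  noisy <- simulate_chronoamperometry(noise = 0.01, seed = 3)
  expect_lt(abs(integrate_charge(noisy$trace) - withcap$truth$q_total) /
              withcap$truth$q_total, 0.005)
})

test_that("assay generator round-trips through the quantifier", {
  a <- simulate_assay_set()
  res <- quantify_nadh(a$set, a$cal_nadh_340, a$cal_rh_340, a$cal_rh_430)
  expect_equal(res$c_nadh, a$truth$c_active, tolerance = 1e-9)
  # with no active species the 340 nm signal is inactive-only
  none <- simulate_assay_set(c_active = 0)
  res0 <- quantify_nadh(none$set, none$cal_nadh_340, none$cal_rh_340,
                        none$cal_rh_430)
  expect_equal(res0$c_nadh, 0, tolerance = 1e-12)
  expect_equal(none$truth$ext_total_340,
               0.013 * 5.0, tolerance = 1e-12)
  expect_error(simulate_assay_set(c_active = -1),
               class = "nadhreg_domain_error")
})

test_that("assay recovery stays accurate under extinction noise", {
  errs <- vapply(1:40, function(s) {
    a <- simulate_assay_set(noise = 0.005, seed = s)
    res <- quantify_nadh(a$set, a$cal_nadh_340, a$cal_rh_340, a$cal_rh_430)
    abs(res$c_nadh - a$truth$c_active) / a$truth$c_active
  }, numeric(1))
  expect_lt(stats::median(errs), 0.03)
})

test_that("bundles are internally consistent and deterministic", {
  b <- make_bundle(seed = 21)
  expect_equal(b$truth$q_theo / b$truth$q_total, b$truth$eta_f,
               tolerance = 1e-12)
  expect_equal(b$truth$q_faradaic + b$truth$q_capacitive,
               b$truth$q_total, tolerance = 1e-12)
  expect_identical(b, make_bundle(seed = 21))
  expect_false(identical(b$chrono,
                         make_bundle(list(noise_chrono = 0.01),
                                     seed = 22)$chrono))
  expect_error(make_bundle(list(selectivity = 0)),
               class = "nadhreg_domain_error")
})

test_that("generators leave the global RNG state untouched", {
  set.seed(99)
  expected <- rnorm(3)
  set.seed(99)
  invisible(simulate_eis(eec_preset("EEC_A"), eec_true_params$EEC_A,
                         noise = 0.01, seed = 7))
  invisible(simulate_chronoamperometry(noise = 0.01, seed = 8))
  invisible(simulate_assay_set(noise = 0.01, seed = 9))
  expect_identical(rnorm(3), expected)
})
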