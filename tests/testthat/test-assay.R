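cal <- function(m, b = 0, species = "x", wl = 340) {
  conc <- seq(0, 0.5, by = 0.1)
  fit_calibration(conc, m * conc + b, species, wl)
}

test_that("calibration lines are recovered exactly and errors flagged", {
  cc <- cal(6.3, 0.02)
  expect_equal(cc$m, 6.3, tolerance = 1e-12)
  expect_equal(cc$b, 0.02, tolerance = 1e-12)
  expect_equal(cc$r_squared, 1, tolerance = 1e-12)
  expect_true(cc$usable)
  expect_error(fit_calibration(c(0.1, 0.1), c(0.5, 0.6)),
               class = "nadhreg_rank_deficient")
  flat <- fit_calibration(c(0, 0.1, 0.2), c(0.3, 0.3, 0.3))
  expect_false(flat$usable)       # zero slope violates the invariant
})

test_that("the four-step assay inversion reproduces hand-worked values", {
  # the worked case: m_Rh430=0.5, m_Rh340=0.2, m_NADH340=6.3, offsets 0
  set <- assay_solution_set(
    ext_340 = c(D = 0.60, E = 0.18),
    ext_430 = c(D = 0.44, E = 0.40))
  res <- quantify_nadh(set, cal(6.3), cal(0.2), cal(0.5, wl = 430))
  expect_equal(res$delta_c_rh, 0.10, tolerance = 1e-9)
  expect_equal(res$d_ext_rh_340, 0.016, tolerance = 1e-9)
  expect_equal(res$ext_nadh_340, 0.404, tolerance = 1e-9)
  # c = (0.404/0.8 - 0)/6.3, the mediator correction carrying its 0.8
  # dilution factor as printed
  expect_equal(res$c_nadh, 0.0801587301587302, tolerance = 1e-9)
  expect_length(res$warnings, 0)
})

test_that("null assay and sign propagation behave as specified", {
  null <- assay_solution_set(c(D = 0.3, E = 0.3), c(D = 0.2, E = 0.2))
  res <- quantify_nadh(null, cal(6.3), cal(0.2), cal(0.5, wl = 430))
  expect_equal(res$delta_c_rh, 0)
  expect_equal(res$c_nadh, 0)
  # E > D at 340 nm with no mediator change: negative c plus warning
  inv <- assay_solution_set(c(D = 0.2, E = 0.3), c(D = 0.2, E = 0.2))
  res2 <- quantify_nadh(inv, cal(6.3), cal(0.2), cal(0.5, wl = 430))
  expect_lt(res2$c_nadh, 0)
  expect_length(res2$warnings, 1)
  # strict_rh_offset = FALSE drops the 340 nm offset when delta_c_Rh = 0
  res3 <- quantify_nadh(null, cal(6.3), cal(0.2, b = 0.01),
                        cal(0.5, wl = 430), strict_rh_offset = FALSE)
  expect_equal(res3$d_ext_rh_340, 0)
  res4 <- quantify_nadh(null, cal(6.3), cal(0.2, b = 0.01),
                        cal(0.5, wl = 430), strict_rh_offset = TRUE)
  expect_equal(res4$d_ext_rh_340, 0.008)  # b * 0.8, as printed
  expect_error(assay_solution_set(c(D = 0.3), c(D = 0.2, E = 0.2)),
               class = "nadhreg_input_error")
})

test_that("selectivity is a clamped, scale-invariant absorbance fraction", {
  expect_equal(as.numeric(selectivity_from_extinctions(0.5, 0.5)), 1.0)
  expect_equal(as.numeric(selectivity_from_extinctions(0.25, 0.5)), 0.5)
  expect_equal(as.numeric(selectivity_from_extinctions(0.404, 0.408)),
               0.404 / 0.408)
  for (lambda in c(0.1, 3, 1000)) {
    expect_equal(
      as.numeric(selectivity_from_extinctions(0.404 * lambda, 0.408 * lambda)),
      0.404 / 0.408, tolerance = 1e-12)
  }
  over <- selectivity_from_extinctions(0.6, 0.5)
  expect_equal(as.numeric(over), 1)
  expect_length(attr(over, "warnings"), 1)
  expect_error(selectivity_from_extinctions(0.4, 0),
               class = "nadhreg_undefined_selectivity")
})

test_that("charge integration matches closed forms", {
  flat <- chronoamperogram(seq(0, 1800, by = 1), rep(-1e-3, 1801))
  expect_equal(integrate_charge(flat), 1.8, tolerance = 1e-12)
  # i(t) = k / sqrt(t): integral 2k(sqrt(t2) - sqrt(t1))
  tt <- seq(1, 1800, length.out = 20000)
  cot <- chronoamperogram(tt, -1e-3 / sqrt(tt))
  expect_equal(integrate_charge(cot), 2e-3 * (sqrt(1800) - 1),
               tolerance = 1e-4)
  expect_error(integrate_charge(chronoamperogram(0, -1e-3)),
               class = "nadhreg_insufficient_data")
})

test_that("Faraday efficiency implements Q_theo = 2 F n over Q_total", {
  # 1 umol of 1,4-NADH needs 2 * 96485 * 1e-6 = 0.19297 C
  fe <- faraday_efficiency(c_nadh = 0.05, volume = 0.02,
                           q_total = 0.19297)
  expect_equal(fe$n_nadh_mol, 1e-6, tolerance = 1e-12)
  expect_equal(fe$eta_f, 1.0, tolerance = 1e-9)
  expect_equal(faraday_efficiency(0.05, 0.02, 2 * 0.19297)$eta_f, 0.5,
               tolerance = 1e-9)
  expect_equal(faraday_efficiency(0, 0.02, 1)$eta_f, 0)
  expect_length(faraday_efficiency(0.05, 0.02, 0.1)$warnings, 1)
  expect_error(faraday_efficiency(0.05, 0.02, 0),
               class = "nadhreg_domain_error")
})

test_that("eta_F is invariant to the unit system of its inputs", {
  # recompute with currents in mA and volume in mL, converted explicitly
  tt <- seq(0, 1800, by = 2)
  i_A <- -(1e-3 + 5e-4 * exp(-tt / 5))
  q_A <- integrate_charge(chronoamperogram(tt, i_A))
  q_from_mA <- integrate_charge(chronoamperogram(tt, (i_A * 1e3) * 1e-3))
  eta1 <- faraday_efficiency(0.2, 0.02, q_A)$eta_f
  eta2 <- faraday_efficiency(0.2 , (20) * 1e-3, q_from_mA)$eta_f
  expect_equal(eta1, eta2, tolerance = 1e-12)
})

test_that("production rate does the unit arithmetic", {
  expect_equal(production_rate(1e-6, area = 4, duration = 1800), 0.5)
  expect_equal(production_rate(0, 4, 1800), 0)
  expect_error(production_rate(1e-6, 4, 0), class = "nadhreg_domain_error")
  expect_error(production_rate(1e-6, 0, 1800),
               class = "nadhreg_domain_error")
})

test_that("assay extinctions scale linearly when offsets are zero", {
  base <- simulate_assay_set()
  for (lambda in c(0.5, 2)) {
    scaled <- simulate_assay_set(c_active = 0.2 * lambda,
                                 c_inactive = 0.013 * lambda)
    r1 <- quantify_nadh(base$set, base$cal_nadh_340, base$cal_rh_340,
                        base$cal_rh_430)
    r2 <- quantify_nadh(scaled$set, scaled$cal_nadh_340,
                        scaled$cal_rh_340, scaled$cal_rh_430)
    expect_equal(r2$ext_nadh_340 / r1$ext_nadh_340, lambda,
                 tolerance = 1e-9)
  }
})
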