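test_that("a gaussian cathodic peak on a linear baseline is located", {
  seg <- gaussian_peak_segment(center = -1.10, amplitude = -2e-5)
  pks <- detect_peaks(seg, search_window = c(-1.3, -0.9))
  expect_length(pks, 1)
  expect_lt(abs(pks[[1]]$E_p - (-1.10)), 0.005)
  expect_lt(abs(pks[[1]]$i_p - (-2e-5)) / 2e-5, 0.05)
  expect_lt(pks[[1]]$i_p, 0)            # cathodic peaks are negative
})

test_that("peak detection is invariant to an added linear baseline", {
  seg <- gaussian_peak_segment(slope = 0, intercept = 0)
  shifted <- seg
  shifted$current <- seg$current + 5e-6 + 3e-6 * seg$potential
  p1 <- detect_peaks(seg, search_window = c(-1.3, -0.9))
  p2 <- detect_peaks(shifted, search_window = c(-1.3, -0.9))
  expect_equal(p2[[1]]$E_p, p1[[1]]$E_p, tolerance = 1e-12)
  expect_equal(p2[[1]]$i_p, p1[[1]]$i_p, tolerance = 1e-9)
})

test_that("flat segments and sub-prominence peaks yield no detections", {
  flat <- structure(list(potential = seq(0, -1, by = -0.01),
                         current = rep(-1e-7, 101),
                         direction = "cathodic"), class = "cv_segment")
  expect_length(detect_peaks(flat), 0)
  # peak at half the prominence threshold is rejected
  seg <- gaussian_peak_segment(amplitude = -5e-6, slope = 0, intercept = 0)
  expect_length(detect_peaks(seg, min_prominence = 1e-5,
                             search_window = c(-1.3, -0.9)), 0)
  expect_error(detect_peaks(flat, search_window = c(2, 3)),
               class = "nadhreg_window_error")
  short <- structure(list(potential = c(0, -0.1, -0.2),
                          current = c(0, 0, 0), direction = "cathodic"),
                     class = "cv_segment")
  expect_error(detect_peaks(short), class = "nadhreg_insufficient_data")
})

test_that("peak-shift regression recovers the printed alpha*n values", {
  nus <- c(0.025, 0.05, 0.1, 0.2, 0.4, 1)
  # points placed exactly on a -59.3 mV/decade line (NAD+ reduction case)
  pts <- data.frame(nu = nus, E_p = -1.1 - 0.0593 * log10(nus / 0.1))
  fit <- peak_shift_fit(pts, temperature = 293)
  expect_equal(round(fit$alpha_n, 2), 0.49)
  expect_equal(fit$slope, -0.0593, tolerance = 1e-12)
  expect_length(fit$warnings, 0)
  # -19.3 mV/decade (mediator reduction case, > 1 electron)
  pts2 <- data.frame(nu = nus, E_p = -0.75 - 0.0193 * log10(nus / 0.1))
  expect_equal(round(peak_shift_fit(pts2, 293)$alpha_n, 2), 1.51)
  # self-consistency: alpha_n * |slope| = 2.303*R*T/(2F) by construction
  for (f in list(fit, peak_shift_fit(pts2, 293))) {
    expect_equal(f$alpha_n * abs(f$slope), peak_shift_constant(293),
                 tolerance = 1e-9)
  }
})

test_that("peak-shift fit rejects degenerate inputs and flags direction", {
  expect_error(peak_shift_fit(data.frame(nu = c(0.1, 0.1),
                                         E_p = c(-1.1, -1.15))),
               class = "nadhreg_insufficient_data")
  expect_error(peak_shift_fit(data.frame(nu = c(-0.1, 0.2),
                                         E_p = c(-1.1, -1.15))),
               class = "nadhreg_domain_error")
  anodic <- peak_shift_fit(data.frame(nu = c(0.1, 1), E_p = c(-1.15, -1.1)))
  expect_length(anodic$warnings, 1)
})

test_that("two-point formula agrees with the regression and is symmetric", {
  an <- two_point_alpha_n(-1.1, 0.1, -1.1593, 1, temperature = 293)
  expect_equal(round(an, 2), 0.49)
  expect_equal(an, two_point_alpha_n(-1.1593, 1, -1.1, 0.1, 293))
  fit2 <- peak_shift_fit(data.frame(nu = c(0.1, 1), E_p = c(-1.1, -1.1593)),
                         293)
  # ln vs log10 conversion is internal: both routes agree exactly
  expect_equal(an, fit2$alpha_n, tolerance = 1e-12)
  expect_error(two_point_alpha_n(-1.1, 0.1, -1.2, 0.1),
               class = "nadhreg_nonidentifiable")
  expect_error(two_point_alpha_n(-1.1, 0.1, -1.1, 0.2),
               class = "nadhreg_nonidentifiable")
})

test_that("peak current vs sqrt(scan rate) flags diffusion control", {
  nus <- c(0.025, 0.05, 0.1, 0.2, 0.4, 1)
  k <- -1e-4
  exact <- scan_rate_current_fit(data.frame(nu = nus, i_p = k * sqrt(nus)))
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-18)
  expect_true(exact$diffusion_controlled)
  noisy <- withr::with_seed(42, {
    scan_rate_current_fit(data.frame(
      nu = nus, i_p = k * sqrt(nus) * (1 + 0.05 * rnorm(6))))
  })
  expect_gt(noisy$r_squared, 0.9)
  expect_lt(noisy$r_squared, 1)
  expect_lt(abs(noisy$slope - k) / abs(k), 0.10)
  expect_error(scan_rate_current_fit(data.frame(nu = 0.1, i_p = -1e-5)),
               class = "nadhreg_insufficient_data")
})
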