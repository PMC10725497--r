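test_that("containers validate their invariants", {
  expect_s3_class(
    cyclic_voltammogram(c(0, -0.1, -0.2), c(0, -1e-6, -2e-6), 0.1),
    "cyclic_voltammogram")
  expect_error(cyclic_voltammogram(c(0, -0.1), c(0, -1e-6), 0.1),
               class = "nadhreg_insufficient_data")
  expect_error(cyclic_voltammogram(c(0, -0.1, -0.2), c(0, -1e-6, -2e-6), -1),
               class = "nadhreg_domain_error")
  expect_error(cyclic_voltammogram(c(0, -0.1, -0.2), c(0, -1e-6), 0.1),
               class = "nadhreg_format_error")
  expect_error(chronoamperogram(c(0, 2, 1), c(1, 2, 3) * -1e-3),
               class = "nadhreg_format_error")
  expect_error(impedance_spectrum(c(1, 0.5, 2), rep(1 + 0i, 3)),
               class = "nadhreg_format_error")
  expect_error(impedance_spectrum(c(0, 1), rep(1 + 0i, 2)),
               class = "nadhreg_domain_error")
})

test_that("delimited tables read with column mapping, units and errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("E,I", "0,0", "-100,-1", "-200,-2"), path)
  cv <- read_electrochem_table(path, "cv",
                               column_map = c(potential = "E", current = "I"),
                               units = c(potential = "mV", current = "uA"),
                               scan_rate = 0.1)
  expect_equal(cv$potential, c(0, -0.1, -0.2))
  expect_equal(cv$current, c(0, -1e-6, -2e-6))
  expect_error(
    read_electrochem_table(path, "cv",
                           column_map = c(potential = "E", current = "amps"),
                           scan_rate = 0.1),
    class = "nadhreg_format_error")
  expect_error(
    read_electrochem_table(path, "cv", column_map = c(potential = "E"),
                           scan_rate = 0.1),
    class = "nadhreg_format_error")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("E,I", "0,0", "-0.1,oops", "-0.2,-2e-6"), bad)
  expect_error(
    read_electrochem_table(bad, "cv",
                           column_map = c(potential = "E", current = "I"),
                           scan_rate = 0.1),
    regexp = "row 2", class = "nadhreg_parse_error")
  # tab-delimited auto-detection
  tabf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t\ti", "0\t-1e-3", "1\t-1e-3", "2\t-1e-3"), tabf)
  ch <- read_electrochem_table(tabf, "chrono",
                               column_map = c(time = "t", current = "i"))
  expect_equal(ch$current, rep(-1e-3, 3))
})

test_that("write/read round trip is lossless within 1e-12 relative", {
  sim <- simulate_irreversible_cv(scan_rate = 0.2, dE = 0.02)
  path <- withr::local_tempfile(fileext = ".csv")
  write_electrochem_table(sim$cv, path)
  back <- read_electrochem_table(path, "cv",
                                 column_map = c(potential = "potential",
                                                current = "current"),
                                 scan_rate = 0.2)
  expect_equal(back$potential, sim$cv$potential, tolerance = 1e-12)
  expect_equal(back$current, sim$cv$current, tolerance = 1e-12)

  spec <- impedance_of(eec_preset("EEC_A"), eec_true_params$EEC_A,
                       10^seq(0, 4, length.out = 21))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_electrochem_table(spec, path2)
  back2 <- read_electrochem_table(path2, "eis",
                                  column_map = c(frequency = "frequency",
                                                 z_re = "z_re",
                                                 z_im = "z_im"))
  expect_equal(back2$z, spec$z, tolerance = 1e-12)
})

test_that("sweep segmentation partitions the triangular waveform", {
  # the study waveform: 0 -> -1.8 -> 1.0 -> 0 gives exactly 3 sweeps
  pot <- c(seq(0, -1.8, by = -0.01), seq(-1.79, 1, by = 0.01),
           seq(0.99, 0, by = -0.01))
  cv <- cyclic_voltammogram(pot, -1e-6 * pot, 0.1)
  segs <- segment_sweeps(cv)
  expect_length(segs, 3)
  expect_equal(vapply(segs, `[[`, "", "direction"),
               c("cathodic", "anodic", "cathodic"))
  # concatenation restores the trace
  expect_equal(unlist(lapply(segs, `[[`, "potential")), pot)
  # each segment monotonic
  for (s in segs) {
    expect_true(all(diff(s$potential) < 0) || all(diff(s$potential) > 0))
  }
  # monotonic ramp -> one segment; constant trace -> degenerate error
  expect_length(segment_sweeps(ramp_cv()), 1)
  expect_error(
    segment_sweeps(cyclic_voltammogram(rep(0, 5), rep(0, 5), 0.1)),
    class = "nadhreg_degenerate_waveform")
})

test_that("segmentation tolerates sub-threshold potential jitter", {
  pot <- seq(0, -1, by = -0.005)
  pot[100] <- pot[100] + 4e-4            # instrument jitter below 1 mV
  cv <- cyclic_voltammogram(pot, -1e-6 * seq_along(pot), 0.1)
  expect_length(segment_sweeps(cv), 1)
})

test_that("replicate aggregation computes mean and sample sd", {
  cvs <- list(ramp_cv(-1e-6), ramp_cv(-2e-6), ramp_cv(-3e-6))
  rs <- aggregate_replicates(cvs)
  expect_equal(unique(rs$current_mean), -2e-6)
  expect_equal(unique(rs$current_sd), 1e-6)  # sd of {1,2,3} uA is 1 uA
  expect_identical(attr(rs, "n_replicates"), 3L)

  same <- aggregate_replicates(list(ramp_cv(), ramp_cv(), ramp_cv()))
  expect_equal(max(same$current_sd), 0)
  expect_equal(unique(same$current_mean), -1e-6)

  expect_error(aggregate_replicates(list(ramp_cv())),
               class = "nadhreg_insufficient_replicates")
  expect_error(
    aggregate_replicates(list(ramp_cv(scan_rate = 0.1),
                              ramp_cv(scan_rate = 0.2))),
    class = "nadhreg_incompatible")
})
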