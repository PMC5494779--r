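test_that("IOP-to-impedance map interpolates linearly between endpoints", {
  cal <- iop_calibration()
  expect_equal(iop_to_impedances(10, cal)[["Z2"]], 1.5393)
  expect_equal(iop_to_impedances(50, cal)[["Z1"]], 1.5519)
  expect_equal(iop_to_impedances(30, cal)[["Z2"]], (1.5393 + 1.5698) / 2)
  expect_equal(iop_to_impedances(30, cal)[["Z1"]], (1.5399 + 1.5519) / 2)
  expect_error(iop_to_impedances(60, cal), "within")
  expect_error(iop_to_impedances(5, cal), "within")
})

test_that("endpoint calibration solves Z0, A0 and posterior gain consistently", {
  cb <- default_calib()
  # the ratio equation must be satisfied essentially exactly
  ratio <- reflection_coefficient(cb$Z0, 1.5519) /
    reflection_coefficient(cb$Z0, 1.5399)
  expect_lt(abs(ratio - 2.1454 / 1.6347), 1e-10)
  # frozen values computed by the same root-finding procedure run
  # standalone (uniroot on the ratio equation, residual < 1e-14)
  expect_equal(cb$Z0, 1.5021153, tolerance = 1e-6)
  expect_equal(cb$A0, 131.6085, tolerance = 1e-6)
  expect_identical(cb$Z3, cb$Z0)
  # forward amplitudes at both endpoints reproduce the calibration inputs
  a_low <- forward_amplitudes(cb$stack_at(10))
  a_high <- forward_amplitudes(cb$stack_at(50))
  expect_equal(a_low[["A1"]], 1.6347, tolerance = 1e-9)
  expect_equal(a_high[["A1"]], 2.1454, tolerance = 1e-9)
  expect_equal(a_low[["Ar"]], 0.5778, tolerance = 1e-9)
})

test_that("endpoint calibration inverts a constructed forward map exactly", {
  # build amplitudes from a chosen Z0* and check it is recovered
  for (Z0_true in c(1.45, 1.50, 1.52)) {
    cal <- iop_calibration()
    a_low <- reflection_coefficient(Z0_true, cal$Z1_low)
    a_high <- reflection_coefficient(Z0_true, cal$Z1_high)
    cb <- calibrate_endpoints(a_low, a_high, post_amp_low = 0.01, cal = cal)
    expect_equal(cb$Z0, Z0_true, tolerance = 1e-9)
    expect_equal(cb$A0, 1, tolerance = 1e-9)
  }
  expect_error(calibrate_endpoints(1, 1, 0.5), "ratio")
})

test_that("generated pulse has unit envelope, stated bandwidth and center frequency", {
  tspec <- transducer_spec()
  dt <- 1e-9
  p <- gaussian_pulse(tspec, dt)
  expect_equal(max(abs(p$samples)), 1, tolerance = 1e-9)  # center sample, cos = 1
  # spectrum: -6 dB (half-amplitude) full width and peak location
  n <- 2^16
  s <- c(p$samples, numeric(n - length(p$samples)))
  spec <- Mod(fft(s))[1:(n / 2)]
  freq <- (seq_len(n / 2) - 1) / (n * dt)
  pk <- which.max(spec)
  expect_lt(abs(freq[pk] - 4.7e7), 1 / (n * dt) + 1e-6)
  above <- which(spec >= 0.5 * spec[pk])
  width <- freq[max(above)] - freq[min(above)]
  expect_equal(width, 0.62 * 4.7e7, tolerance = 0.02)
  expect_error(gaussian_pulse(tspec, dt = 1e-7), "sampling rate")
})

test_that("simulated A-line carries both echoes at the modelled amplitudes and delay", {
  cb <- default_calib()
  st <- cb$stack_at(30)
  tspec <- transducer_spec()
  aspec <- quiet_aspec()
  rec <- simulate_aline(st, tspec, aspec, iop = 30)
  env <- analytic_envelope(rec)
  truth <- forward_amplitudes(st)
  # dense-grid oracle for the two envelope peak times
  w <- detect_echoes(env, rec$dt)
  o_ant <- upsampled_argmax(env, w$anterior, rec$dt)
  o_post <- upsampled_argmax(env, w$posterior, rec$dt)
  tau_sep <- 2 * st$cornea_thickness / st$cornea_speed
  expect_lt(abs((o_post$tof - o_ant$tof) - tau_sep), rec$dt)
  expect_equal(o_ant$amplitude, truth[["A1"]], tolerance = 5e-3)
  expect_equal(o_post$amplitude, truth[["Ar"]], tolerance = 5e-3)
})

test_that("matched anterior impedance suppresses the anterior echo", {
  cb <- default_calib()
  st <- layer_stack(Z0 = 1.5, Z1 = 1.5, Z2 = 1.56, Z3 = 1.5,
                    posterior_gain = cb$posterior_gain, A0 = cb$A0)
  rec <- simulate_aline(st, transducer_spec(), quiet_aspec(), iop = 30)
  env <- analytic_envelope(rec)
  tau_a <- 0.5e-6
  i_a <- round(tau_a / rec$dt) + 1
  # bounded by the analytic-signal leakage floor, far below any real echo
  expect_lt(max(env[(i_a - 50):(i_a + 50)]), 1e-4)
})

test_that("anterior echo amplitude grows strictly with impedance contrast", {
  Z0 <- 1.5
  amps <- sapply(seq(1.51, 1.8, by = 0.02), function(Z1) {
    st <- layer_stack(Z0 = Z0, Z1 = Z1, Z2 = Z1 + 0.02, Z3 = Z0, A0 = 10)
    forward_amplitudes(st)[["A1"]]
  })
  expect_true(all(diff(amps) > 0))
})

test_that("simulation is reproducible under a fixed seed and rejects bad geometry", {
  cb <- default_calib()
  aspec <- acquisition_spec(n_alines = 2L, n_repeats = 1L, seed = 7L)
  s1 <- simulate_experiment(cb, aspec = aspec, iops = c(10, 30))
  s2 <- simulate_experiment(cb, aspec = aspec, iops = c(10, 30))
  expect_identical(lapply(s1$records, `[[`, "samples"),
                   lapply(s2$records, `[[`, "samples"))
  # unresolvable echoes: transit time shorter than the pulse
  st_thin <- layer_stack(Z0 = 1.5, Z1 = 1.54, Z2 = 1.55, Z3 = 1.5,
                         cornea_thickness = 5e-5, A0 = 1)
  expect_error(simulate_aline(st_thin, transducer_spec(), quiet_aspec(), 10),
               "unresolvable")
})

test_that("experiment design counts multiply out and manifests are deterministic", {
  cb <- default_calib()
  sim <- simulate_experiment(cb, aspec = acquisition_spec(seed = 5L))
  expect_length(sim$records, 5 * 3 * 10)
  sim1 <- simulate_experiment(cb, aspec = quiet_aspec(seed = 3L), iops = 20)
  expect_length(sim1$records, 1L)
  # dataset round-trip: byte-identical manifests, identical samples
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- write_aline_dataset(sim1, d1)
  m2 <- write_aline_dataset(simulate_experiment(
    cb, aspec = quiet_aspec(seed = 3L), iops = 20), d2)
  expect_identical(readLines(m1), readLines(m2))
  back <- read_aline_dataset(d1)
  expect_equal(back[[1]]$samples, sim1$records[[1]]$samples, tolerance = 1e-15)
  expect_equal(back[[1]]$iop, 20)
  expect_error(simulate_experiment(cb, aspec = quiet_aspec(), iops = 99),
               "calibrated range")
})

test_that("quartz reference echo follows the single-interface model", {
  cb <- default_calib()
  st <- cb$stack_at(10)
  rec <- simulate_reference_echo(2650, 5750, st)
  env <- analytic_envelope(rec)
  # Zq = 2650 * 5750 / 1e6 = 15.2375 MRayl; R(Z0, Zq) computed directly
  Zq <- 15.2375
  expect_equal(reflection_coefficient(1.502, Zq), 0.8205, tolerance = 1e-3)
  expect_equal(max(env), st$A0 * reflection_coefficient(st$Z0, Zq),
               tolerance = 2e-3)
  # linearity in A0
  st2 <- st; st2$A0 <- 2 * st$A0
  rec2 <- simulate_reference_echo(2650, 5750, st2)
  expect_equal(max(abs(rec2$samples)), 2 * max(abs(rec$samples)),
               tolerance = 1e-12)
  # matched quartz: no echo
  stq <- layer_stack(Z0 = 1.5, Z1 = 1.54, Z2 = 1.55, Z3 = 1.5, A0 = 1)
  recq <- simulate_reference_echo(1.5e6 / 1e3, 1e3, stq)  # Zq = 1.5 MRayl
  expect_equal(max(abs(recq$samples)), 0)
})

test_that("noiseless envelope peaks match closed-form amplitudes within the ripple bound", {
  cb <- default_calib()
  for (iop in c(10, 30, 50)) {
    st <- cb$stack_at(iop)
    rec <- simulate_aline(st, transducer_spec(), quiet_aspec(), iop)
    f <- extract_features(list(rec))
    truth <- forward_amplitudes(st)
    expect_lt(abs(f$ant_amp / truth[["A1"]] - 1), 0.005)
    expect_lt(abs(f$post_amp / truth[["Ar"]] - 1), 0.005)
    expect_lt(abs(f$tof_diff_s - 2 * st$cornea_thickness / st$cornea_speed),
              rec$dt)
  }
})
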