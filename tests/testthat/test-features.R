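test_that("analytic envelope recovers the Gaussian envelope of a modulated pulse", {
  dt <- 1e-9
  sigma <- 15e-9
  t <- (0:1999) * dt
  g <- exp(-(t - 1e-6)^2 / (2 * sigma^2))
  x <- g * cos(2 * pi * 4.7e7 * (t - 1e-6))
  env <- analytic_envelope(x)
  core <- which(g > 0.01)           # away from record edges
  expect_lt(max(abs(env[core] - g[core]) / max(g)), 0.01)
  expect_identical(analytic_envelope(numeric(100)), numeric(100))
  expect_equal(analytic_envelope(-x), env, tolerance = 1e-12)
  expect_error(analytic_envelope(numeric(0)), "empty")
})

test_that("echo detection finds two separated peaks and errors otherwise", {
  dt <- 1e-9
  t <- (0:2999) * dt
  mk <- function(centers, amps) {
    s <- numeric(length(t))
    for (i in seq_along(centers))
      s <- s + amps[i] * exp(-(t - centers[i])^2 / (2 * (15e-9)^2)) *
        cos(2 * pi * 4.7e7 * (t - centers[i]))
    s
  }
  env <- analytic_envelope(mk(c(0.8e-6, 1.8e-6), c(1, 0.4)))
  w <- detect_echoes(env, dt, min_separation = 0.2e-6)
  expect_lt(abs(w$anterior[ceiling(length(w$anterior) / 2)] - 801), 1.5)
  expect_lt(abs(w$posterior[ceiling(length(w$posterior) / 2)] - 1801), 1.5)
  # single echo
  env1 <- analytic_envelope(mk(0.8e-6, 1))
  expect_error(detect_echoes(env1, dt), "found 1")
  # echoes closer than the separation floor
  env2 <- analytic_envelope(mk(c(0.8e-6, 0.88e-6), c(1, 0.5)))
  expect_error(detect_echoes(env2, dt, min_separation = 0.2e-6), "found 1")
})

test_that("parabolic fit recovers exact parabolas and simple symmetric triples", {
  # symmetric triple: vertex at the middle sample
  f <- parabolic_peak_fit(c(0, 1, 2, 1, 0), 2:4, dt = 1, window_frac = 0.2)
  expect_equal(f$tof, 2)            # 0-based sample index times dt = 1
  expect_equal(f$amplitude, 2)
  # exact parabola y = 5 - (x - 7.3)^2 sampled at x = 5..10
  x <- 5:10
  y <- 5 - (x - 7.3)^2
  env <- c(numeric(5), y)           # absolute indices 6..11, x = idx - 1
  f2 <- parabolic_peak_fit(env, 6:11, dt = 1, window_frac = 0.01)
  expect_equal(f2$tof, 7.3, tolerance = 1e-9)
  expect_equal(f2$amplitude, 5, tolerance = 1e-9)
  expect_equal(f2$r2_of_fit, 1, tolerance = 1e-12)
  # edge maximum and starved windows are rejected
  expect_error(parabolic_peak_fit(c(3, 2, 1), 1:3, dt = 1), "edge")
  expect_error(parabolic_peak_fit(c(0, 0.1, 1, 0.1, 0), 2:4, dt = 1,
                                  window_frac = 0.9), "fewer than 3")
})

test_that("parabolic vertex matches a 100x-upsampled argmax oracle on synthetic echoes", {
  cb <- default_calib()
  for (iop in c(10, 50)) {
    st <- cb$stack_at(iop)
    rec <- simulate_aline(st, transducer_spec(), quiet_aspec(), iop)
    env <- analytic_envelope(rec)
    w <- detect_echoes(env, rec$dt)
    for (win in w) {
      fit <- parabolic_peak_fit(env, win, rec$dt)
      oracle <- upsampled_argmax(env, win, rec$dt)
      expect_lt(abs(fit$tof - oracle$tof), 0.5 * rec$dt)
      expect_equal(fit$amplitude, oracle$amplitude, tolerance = 5e-3)
    }
  }
})

test_that("amplitude estimation is exactly scale-equivariant", {
  cb <- default_calib()
  rec <- simulate_aline(cb$stack_at(30), transducer_spec(), quiet_aspec(), 30)
  f1 <- extract_features(list(rec))
  rec$samples <- 3.7 * rec$samples
  f2 <- extract_features(list(rec))
  expect_equal(f2$ant_amp, 3.7 * f1$ant_amp, tolerance = 1e-9)
  expect_equal(f2$post_amp, 3.7 * f1$post_amp, tolerance = 1e-9)
  expect_equal(f2$ant_tof_s, f1$ant_tof_s, tolerance = 1e-9)
})

test_that("posterior echo polarity is reported as inverted when Z2 > Z3", {
  cb <- default_calib()
  rec <- simulate_aline(cb$stack_at(30), transducer_spec(), quiet_aspec(), 30)
  f <- extract_features(list(rec))
  expect_identical(f$polarity_post, -1)
})

test_that("aggregation reduces to the obvious answers on degenerate tables", {
  row <- data.frame(iop_mmHg = 10, eye_id = 1, repeat_id = 1, aline_id = 1:2,
                    ant_amp = 2, ant_tof_s = 1e-6, post_amp = 1,
                    post_tof_s = 2e-6, tof_diff_s = 1e-6, polarity_post = -1)
  agg <- aggregate_features(row)
  expect_equal(agg$ant_amp_mean, 2)
  expect_equal(agg$ant_amp_sd, 0)
  two <- row; two$ant_amp <- c(1, 3)
  expect_equal(aggregate_features(two)$ant_amp_mean, 2)
  expect_error(aggregate_features(row[0, ]), "empty")
})

test_that("per-IOP anterior amplitude means track generator truth under noise", {
  cb <- default_calib()
  sim <- simulate_experiment(cb, aspec = acquisition_spec(seed = 11L))
  agg <- aggregate_features(extract_features(sim))
  for (i in seq_len(nrow(agg))) {
    se <- sim$noise_sd / sqrt(agg$n[i])
    # 3 noise-scaled standard errors, plus the deterministic fit bias bound
    expect_lt(abs(agg$ant_amp_mean[i] - sim$truth$ant_amp[i]),
              3 * se + 0.005 * sim$truth$ant_amp[i])
  }
})

test_that("fitted anterior time of flight repeats within a few nanoseconds across seeds", {
  cb <- default_calib()
  tofs <- sapply(1:8, function(s) {
    sim <- simulate_experiment(cb, aspec = quiet_aspec(seed = s, noise_sd = NA),
                               iops = 30)
    extract_features(sim)$ant_tof_s
  })
  expect_lt(max(tofs) - min(tofs), 10e-9)   # within the +/- 5 ns band
})
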