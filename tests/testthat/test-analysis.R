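test_that("dF/F0 is zero on the baseline, reads percent, and is gain invariant", {
  t <- seq(0, 1, by = 1e-3)
  f <- ifelse(t < 0.5, 2, 4)  # doubling step
  p <- dff0(f, baseline_window = c(0, 0.1), time_s = t)
  expect_equal(p$value[t < 0.4], rep(0, sum(t < 0.4)))
  expect_equal(p$value[t > 0.6], rep(100, sum(t > 0.6)))

  # constant trace: 0 % everywhere
  pc <- dff0(rep(3, length(t)), c(0, 0.1), time_s = t)
  expect_true(all(pc$value == 0))

  # positive gain leaves dF/F0 unchanged to machine precision
  set.seed(5)
  g <- 2 + abs(rnorm(1))
  noisy <- 1 + 0.3 * pmax(t - 0.3, 0) + rnorm(length(t), sd = 0.01)
  p1 <- dff0(noisy, c(0, 0.1), time_s = t)
  p2 <- dff0(g * noisy, c(0, 0.1), time_s = t)
  expect_equal(p1$value, p2$value, tolerance = 1e-12)

  expect_error(dff0(noisy - 10, c(0, 0.1), time_s = t), "baseline mean")
})

test_that("control subtraction cancels shared components exactly", {
  t <- seq(0, 2, by = 1e-3)
  drift <- 0.8 * t          # shared linear drift
  stim <- processed_trace(t, 10 * pmax(t - 1, 0) + drift)
  ctl <- processed_trace(t, drift)
  out <- subtract_control(stim, ctl)
  expect_equal(out$value, 10 * pmax(t - 1, 0), tolerance = 1e-12)
  expect_true(all(subtract_control(stim, stim)$value == 0))
  # zero control is the identity
  z <- processed_trace(t, rep(0, length(t)))
  expect_equal(subtract_control(stim, z)$value, stim$value)
})

test_that("sliding average: constant invariance, impulse plateau, noise reduction", {
  t <- seq(0, 1, by = 1e-3)
  cst <- sliding_average(rep(4, length(t)), 0.08, time_s = t)
  expect_equal(cst$value, rep(4, length(t)))

  imp <- rep(0, length(t)); imp[500] <- 7
  m <- 81  # samples in an 81 ms window
  s <- sliding_average(imp, 0.081, time_s = t)
  expect_equal(s$value[500], 7 / m, tolerance = 1e-12)

  set.seed(21)
  t2 <- seq(0, 20, by = 1e-3)
  w <- rnorm(length(t2))
  sm <- sliding_average(w, 0.081, time_s = t2)
  mid <- 200:19800
  expect_equal(stats::sd(sm$value[mid]) * sqrt(m), 1, tolerance = 0.15)
  expect_error(sliding_average(w, 30, time_s = t2), "longer")
})

test_that("crosstalk estimator: identity 100 %, flat target 0 %, slope recovery", {
  t <- seq(0, 3, by = 1e-3)
  x <- 1 + saturating_rise(t, 0.2, 0.4, 0.5)
  ct <- crosstalk(x, x, window_s = c(0, 2), time_s = t)
  expect_equal(ct$percent, 100, tolerance = 1e-9)
  expect_equal(ct$percent, 100 * ct$slope)

  flat <- crosstalk(x, rep(2, length(t)), window_s = c(0, 2), time_s = t)
  expect_equal(flat$percent, 0, tolerance = 1e-9)

  set.seed(8)
  y <- 0.31 * x + rnorm(length(t), sd = 0.002)
  rec <- crosstalk(x, y, window_s = c(0, 2), time_s = t)
  expect_equal(rec$percent, 31, tolerance = 1)

  # identity holds for arbitrary nonconstant traces
  for (i in 1:10) {
    z <- cumsum(rnorm(500))
    expect_equal(crosstalk(z, z, time_s = seq_along(z) * 1e-3)$percent, 100,
                 tolerance = 1e-9)
  }
  expect_error(crosstalk(rep(1, 100), rnorm(100), time_s = 1:100 * 1e-3),
               "zero variance")
})

test_that("S/N is mean over SD and scale invariant", {
  set.seed(12)
  v <- 10 + rnorm(200)
  s <- snr(v)
  expect_equal(s, 10, tolerance = 2 * 10 / sqrt(2 * 199))  # 2 SE of the SD
  expect_equal(snr(3 * v), s)
  v2 <- 10 + 2 * (v - 10)
  expect_equal(snr(v2), mean(v2) / sd(v2))
  expect_warning(s0 <- snr(rep(5, 200)), "Inf")
  expect_identical(s0, Inf)
})

test_that("ratio trace: identity, per-channel gain invariance, +22.2 % case", {
  t <- seq(0, 1, by = 1e-3)
  base <- 2 + 0.2 * sin(2 * pi * t)
  expect_true(all(abs(ratio_trace(base, base, c(0, 0.1), time_s = t)$value) < 1e-12))

  num <- ifelse(t < 0.5, 1, 1.1)
  den <- ifelse(t < 0.5, 1, 0.9)
  r <- ratio_trace(num, den, c(0, 0.2), time_s = t)
  expect_equal(r$value[t > 0.6], rep((1.1 / 0.9 - 1) * 100, sum(t > 0.6)),
               tolerance = 1e-9)

  r1 <- ratio_trace(num, den, c(0, 0.2), time_s = t)
  r2 <- ratio_trace(3.3 * num, 0.7 * den, c(0, 0.2), time_s = t)
  expect_equal(r1$value, r2$value, tolerance = 1e-12)
  expect_error(ratio_trace(num, den - 1, c(0, 0.2), time_s = t), "index")
})

test_that("monoexponential fit recovers exact parameters and rejects flat input", {
  t <- seq(0, 0.1, by = 1e-4)
  y <- 2 + 3 * exp(-354 * t)
  f <- fit_monoexponential(y, time_s = t)
  expect_equal(f$k_per_s, 354, tolerance = 1e-6)
  expect_equal(f$amplitude, 3, tolerance = 1e-6)
  expect_equal(f$offset, 2, tolerance = 1e-6)

  # rising exponential (negative amplitude) works equally
  y2 <- 5 - 2 * exp(-100 * t)
  f2 <- fit_monoexponential(y2, time_s = t)
  expect_equal(f2$k_per_s, 100, tolerance = 1e-6)
  expect_equal(f2$amplitude, -2, tolerance = 1e-6)

  expect_error(fit_monoexponential(rep(1, length(t)), time_s = t),
               "degenerate")
})

test_that("filtered-trace rate recovery bias is < 1 % across the rate sweep", {
  dt <- 1e-6
  tau <- 1e-4
  t <- seq(0, 0.1, by = dt)
  for (k in c(50, 100, 200, 354)) {
    y <- cascaded_lowpass(1 + 2 * exp(-k * t), tau, 3, dt)
    idx <- seq(1, length(t), by = 100)  # 100 us sampling
    f <- fit_monoexponential(y[idx], t_range = c(0.0015, 0.1),
                             time_s = t[idx])
    expect_lt(abs(f$k_per_s - k) / k, 0.01)
  }
})

test_that("Nernst potential: equal concentrations, tenfold steps, reference value", {
  expect_equal(nernst_potential(423), 0)
  expect_equal(nernst_potential(42.3),
               1000 * 8.3145 * 291.15 / 96485 * log(0.1),
               tolerance = 1e-9)
  expect_equal(nernst_potential(42.3), -57.77, tolerance = 0.01)
  # log-linearity: a tenfold increase adds the same increment anywhere
  d1 <- nernst_potential(100) - nernst_potential(10)
  d2 <- nernst_potential(400) - nernst_potential(40)
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_error(nernst_potential(-5), "positive")
})

test_that("Vm calibration recovers the generating line and converts traces back", {
  EK <- nernst_potential(c(9, 20, 50, 120, 300))
  peaks <- 0.5 * (EK - (-45))
  cal <- suppressWarnings(calibrate_vm(peaks, EK))
  expect_equal(cal$sensitivity_pct_per_mV, 0.5, tolerance = 1e-9)
  expect_equal(cal$V_rest_mV, -45, tolerance = 1e-9)

  # noisy recovery within 2 SEs (fixed seed)
  set.seed(77)
  cal2 <- calibrate_vm(peaks + rnorm(5, sd = 0.5), EK)
  expect_lt(abs(cal2$sensitivity_pct_per_mV - 0.5), 2 * cal2$sensitivity_se)
  expect_lt(abs(cal2$V_rest_mV - (-45)), 2 * cal2$V_rest_se)
  expect_error(calibrate_vm(rep(0, 5), EK), "slope")

  # round trip: voltage -> dF/F0 -> voltage
  t <- seq(0, 1, by = 1e-3)
  v_true <- -45 + pulse_waveform(t, 0.1, 0.02, 0.2, -30)
  dff <- processed_trace(t, 0.5 * (v_true - (-45)))
  v_back <- vm_from_dff(dff, cal)
  expect_equal(v_back$value, v_true, tolerance = 1e-9)
  expect_equal(vm_from_dff(processed_trace(0, 0), cal)$value, -45)
  # hyperpolarization maps below rest for positive sensitivity
  expect_lt(min(v_back$value), -45)
})

test_that("onset detection finds steps, ignores flat noise, orders the cascade", {
  t <- seq(0, 1, by = 1e-3)
  set.seed(3)
  y <- rnorm(length(t), sd = 0.1)
  y[t >= 0.4] <- y[t >= 0.4] + 1  # 10 SD step
  lat <- detect_onset(y, c(0, 0.2), time_s = t)
  expect_equal(lat, 0.4, tolerance = 2e-3)

  expect_true(is.na(detect_onset(rnorm(length(t), sd = 0.1), c(0, 0.2),
                                 time_s = t)))

  # negative-going step auto-detects direction
  y2 <- rnorm(length(t), sd = 0.1)
  y2[t >= 0.3] <- y2[t >= 0.3] - 2
  expect_equal(detect_onset(y2, c(0, 0.2), time_s = t), 0.3, tolerance = 2e-3)
})

test_that("Vm at onset interpolates the calibrated trace", {
  t <- seq(0, 1, by = 1e-3)
  v <- processed_trace(t, -40 - 50 * t, units = "mV")
  expect_equal(vm_at_onset(v, 0.2), -50, tolerance = 1e-9)
  expect_equal(vm_at_onset(v, t[301]), v$value[301])
  expect_error(vm_at_onset(v, 2), "outside")
})
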