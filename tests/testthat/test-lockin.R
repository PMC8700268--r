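test_that("cascaded lowpass has unit DC gain and the closed-form response", {
  dt <- 1e-6
  x <- rep(3.7, 50000)  # 50 ms at 1 MHz, tau 1 ms: > 10 tau per stage
  y <- cascaded_lowpass(x, 1e-3, 3, dt)
  expect_equal(y[length(y)], 3.7, tolerance = 1e-6)

  # closed-form magnitude at 20 log-spaced frequencies, < 2 % relative
  tau <- 1e-3
  t <- seq(0, 0.12, by = dt)
  for (f in 10^seq(log10(30), log10(2e4), length.out = 20)) {
    y <- cascaded_lowpass(sin(2 * pi * f * t), tau, 3, dt)
    ss <- t > 0.06
    meas <- sqrt(2) * stats::sd(y[ss])
    expect_equal(meas, lockin_gain(f, tau, 3), tolerance = 0.02)
  }

  # single-stage -3 dB point
  f3 <- 1 / (2 * pi * tau)
  t2 <- seq(0, 0.2, by = dt)
  y1 <- cascaded_lowpass(sin(2 * pi * f3 * t2), tau, 1, dt)
  g <- 20 * log10(sqrt(2) * stats::sd(y1[t2 > 0.1]))
  expect_equal(g, -3.01, tolerance = 0.05)
  expect_error(cascaded_lowpass(1:10, -1, 3, dt), "positive")
})

test_that("third-order cascade rolls off at 18 dB per octave", {
  dt <- 1e-6; tau <- 1e-3
  f <- 8000  # >= 50 per-stage corner frequencies
  t <- seq(0, 0.2, by = dt)
  a1 <- sqrt(2) * stats::sd(cascaded_lowpass(cos(2 * pi * f * t), tau, 3, dt)[t > 0.1])
  a2 <- sqrt(2) * stats::sd(cascaded_lowpass(cos(2 * pi * 2 * f * t), tau, 3, dt)[t > 0.1])
  slope <- 20 * log10(a1 / a2)
  expect_equal(slope, 18, tolerance = 0.2)
})

test_that("demodulation recovers amplitude, rejects DC, and attenuates a far tone", {
  dt <- 2e-6
  t <- seq(0, 0.05, by = dt)
  f <- 3e4
  mk_raw <- function(y) {
    structure(list(time_s = t, y = matrix(y, ncol = 1,
                                          dimnames = list(NULL, "D1")),
                   dt = dt, meta = list()),
              class = "raw_traces")
  }
  cfg <- lockin_config(5e-4, 3, output_interval_s = 1e-4)
  ch <- demod_channels("a", "D1", f)

  d <- demodulate(mk_raw(5 * cos(2 * pi * f * t)), ch, cfg)
  expect_equal(unname(d$x[nrow(d$x), 1]), 5, tolerance = 1e-4)

  d0 <- demodulate(mk_raw(rep(2, length(t))), ch, cfg,
                   phase_window_s = c(0.02, 0.05))
  expect_lt(max(abs(d0$x[d0$settled, 1])), 1e-5)

  # two tones separated so that 2 pi |f1-f2| tau = 43.4: second tone
  # attenuated by the order-3 closed form
  cfg1 <- lockin_config(1e-3, 3, output_interval_s = 1e-4,
                        phase_mode = 0)
  df <- 43.4 / (2 * pi * 1e-3)  # 6.907 kHz
  y2 <- cos(2 * pi * f * t) + cos(2 * pi * (f + df) * t)
  d2 <- demodulate(mk_raw(y2), ch, cfg1)
  ss <- d2$settled
  ripple <- max(abs(d2$x[ss, 1] - 1))
  expect_lt(ripple, 2 * (1 + 43.4^2)^(-3 / 2) + 1e-5)
})

test_that("demodulation is linear in the raw trace", {
  dt <- 2e-6
  t <- seq(0, 0.03, by = dt)
  f <- 3e4
  mk_raw <- function(y) structure(
    list(time_s = t, y = matrix(y, ncol = 1, dimnames = list(NULL, "D1")),
         dt = dt, meta = list()), class = "raw_traces")
  cfg <- lockin_config(5e-4, 3, output_interval_s = 1e-4, phase_mode = 0)
  ch <- demod_channels("a", "D1", f)
  y1 <- (1 + 0.5 * sin(2 * pi * 40 * t)) * cos(2 * pi * f * t)
  y2 <- cos(2 * pi * f * t + 0.7) + 0.3
  x1 <- demodulate(mk_raw(y1), ch, cfg)$x
  x2 <- demodulate(mk_raw(y2), ch, cfg)$x
  x12 <- demodulate(mk_raw(2 * y1 - 3 * y2), ch, cfg)$x
  expect_equal(x12, 2 * x1 - 3 * x2, tolerance = 1e-12)
})

test_that("auto-phase recovers the generation phase", {
  dt <- 2e-6
  t <- seq(0, 0.02, by = dt)
  f <- 2.5e4
  for (phi0 in c(0, 0.6, -2.2)) {
    raw <- structure(
      list(time_s = t,
           y = matrix(3 * cos(2 * pi * f * t + phi0), ncol = 1,
                      dimnames = list(NULL, "D1")),
           dt = dt, meta = list()), class = "raw_traces")
    phi <- auto_phase(raw, f, c(0, 0.02))
    expect_equal(((phi - phi0 + pi) %% (2 * pi)) - pi, 0, tolerance = 1e-3)
  }
  # adding pi to the generation phase flips the in-phase sign
  mk <- function(p) structure(
    list(time_s = t, y = matrix(cos(2 * pi * f * t + p), ncol = 1,
                                dimnames = list(NULL, "D1")),
         dt = dt, meta = list()), class = "raw_traces")
  cfg <- lockin_config(5e-4, 3, output_interval_s = 1e-4, phase_mode = 0)
  ch <- demod_channels("a", "D1", f)
  xa <- demodulate(mk(0), ch, cfg)$x
  xb <- demodulate(mk(pi), ch, cfg)$x
  expect_equal(xb, -xa, tolerance = 1e-9)
  expect_error(auto_phase(mk(0), f, c(0, 10 / f)), "20 modulation periods")
})

test_that("settling mask covers the step response", {
  cfg <- lockin_config(1e-3, 3, output_interval_s = 1e-3)
  t <- seq(0, 0.1, by = 1e-3)
  m <- settle_mask(cfg, t)
  expect_equal(sum(m), 30)  # first 30 ms masked for tau 1 ms, order 3
  cfg2 <- lockin_config(1e-4, 3, output_interval_s = 1e-4)
  expect_equal(settle_time(cfg2), 3e-3)

  # a step reaches >= 99 % of its final value within the masked span
  dt <- 1e-6
  y <- cascaded_lowpass(rep(1, settle_time(cfg) / dt), 1e-3, 3, dt)
  expect_gte(y[length(y)], 0.99)
})

test_that("demodulated baseline noise scales as tau^(-1/2)", {
  dt <- 1e-5
  t <- seq(0, 2, by = dt)
  f <- 2e4
  set.seed(314)
  y <- cos(2 * pi * f * t) + rnorm(length(t), sd = 1)
  raw <- structure(list(time_s = t,
                        y = matrix(y, ncol = 1, dimnames = list(NULL, "D1")),
                        dt = dt, meta = list()), class = "raw_traces")
  ch <- demod_channels("a", "D1", f)
  sds <- vapply(c(1e-4, 1e-3, 1e-2), function(tau) {
    cfg <- lockin_config(tau, 3, output_interval_s = 1e-2, phase_mode = 0)
    d <- demodulate(raw, ch, cfg)
    stats::sd(d$x[d$time_s > 10 * settle_time(cfg) / 10 + 0.5, 1])
  }, numeric(1))
  expect_equal(sds[1] / sds[2], sqrt(10), tolerance = 0.2 * sqrt(10))
  expect_equal(sds[2] / sds[3], sqrt(10), tolerance = 0.2 * sqrt(10))
})
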