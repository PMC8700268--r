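# a minimal one-probe, one-detector bench for simulator tests
tiny_bench <- function(freqs = c(3e4, 4.3e4), duration = 0.02,
                       rate = 5e5, multiplex = TRUE, background = 0) {
  led <- boxcar_spectrum(460, 500)
  sp <- species("dye", excitation = boxcar_spectrum(450, 510),
                emission = boxcar_spectrum(520, 560))
  exch <- lapply(seq_along(freqs), function(i) {
    excitation_channel(paste0("ch", i), led, "485/20", freqs[i])
  })
  det <- list(detection_channel("D1", list("540/30")))
  cfg <- acquisition_config(exch, det, duration_s = duration,
                            sim_rate_hz = rate, multiplex_enabled = multiplex,
                            background = background)
  S <- build_coupling_tensor(list(sp), exch, det)
  list(cfg = cfg, S = S, sp = sp)
}

const_kin <- function(duration, value = 1, name = "dye") {
  t <- seq(0, duration, by = 1e-3)
  concentration_traces(t, matrix(value, length(t), 1,
                                 dimnames = list(NULL, name)))
}

test_that("LED intensity has the stated extremes, mean and control mode", {
  exch <- excitation_channel("x", gaussian_band(490, 25), "485/20",
                             mod_freq_hz = 1e4, mod_depth = 1, intensity = 2)
  # integer number of periods
  t <- seq(0, 10 / 1e4, length.out = 20001)[-20001]
  I <- led_intensity(exch, t)
  expect_equal(min(I), 0, tolerance = 1e-6)
  expect_equal(max(I), 2, tolerance = 1e-6)
  expect_equal(mean(I), 1, tolerance = 1e-6)  # intensity / 2

  # control condition: all channels forced onto one common frequency
  I2 <- led_intensity(exch, t, multiplex_enabled = FALSE, common_freq_hz = 2.2e4)
  sp <- Mod(stats::fft(I2 - mean(I2)))
  fgrid <- (seq_along(t) - 1) / (length(t) * (t[2] - t[1]))
  expect_equal(fgrid[which.max(sp[1:(length(t) / 2)])], 2.2e4, tolerance = 100)
  expect_error(led_intensity(exch, t, sim_rate_hz = 1.5e4), "Nyquist")
})

test_that("noiseless simulation is an exact sum of raised cosines", {
  b <- tiny_bench(background = 0.7)
  kin <- const_kin(0.02)
  raw <- simulate_acquisition(b$cfg, b$S, kin)
  t <- raw$time_s
  expected <- 0.7
  for (j in 1:2) {
    f <- b$cfg$excitation_channels[[j]]$mod_freq_hz
    expected <- expected + b$S[1, j, 1] * (1 + cos(2 * pi * f * t)) / 2
  }
  expect_equal(raw$y[, 1], expected, tolerance = 1e-9)
})

test_that("forward map is linear in the concentrations and zero tensor gives background", {
  b <- tiny_bench()
  k1 <- const_kin(0.02, 1)
  k2 <- const_kin(0.02, 2.5)
  y1 <- simulate_acquisition(b$cfg, b$S, k1)$y
  y2 <- simulate_acquisition(b$cfg, b$S, k2)$y
  expect_equal(y2, 2.5 * y1, tolerance = 1e-9)

  S0 <- b$S * 0
  raw0 <- simulate_acquisition(b$cfg, S0, k1,
                               noise_spec(dark_sd = 0.1, seed = 4))
  expect_equal(mean(raw0$y), 0, tolerance = 0.01)
  expect_equal(sd(raw0$y), 0.1, tolerance = 0.01)
})

test_that("identical seed and config reproduce the traces bit-identically", {
  b <- tiny_bench()
  kin <- const_kin(0.02)
  n <- noise_spec(shot_scale = 0.5, dark_sd = 0.2, seed = 99)
  r1 <- simulate_acquisition(b$cfg, b$S, kin, n)
  r2 <- simulate_acquisition(b$cfg, b$S, kin, n)
  expect_identical(r1$y, r2$y)
  r3 <- simulate_acquisition(b$cfg, b$S, kin,
                             noise_spec(0.5, 0.2, seed = 100))
  expect_false(identical(r1$y, r3$y))
})

test_that("noiseless spectrum is pure: only DC and the channel frequencies", {
  b <- tiny_bench(freqs = c(2e4, 5e4), duration = 0.01, rate = 5e5)
  raw <- simulate_acquisition(b$cfg, b$S, const_kin(0.01))
  n <- nrow(raw$y)
  sp <- Mod(stats::fft(raw$y[, 1]))[1:(n / 2)]
  fgrid <- (0:(n / 2 - 1)) / (n / b$cfg$sim_rate_hz)
  keep <- round(fgrid) %in% c(0, 20000, 50000)
  expect_lt(max(sp[!keep]), 1e-9 * max(sp))
})

test_that("flash artifact is visible raw, recorded in metadata, and rejected demodulated", {
  b <- tiny_bench(freqs = 3e4, duration = 0.1, rate = 5e5)
  kin <- const_kin(0.1)
  raw <- simulate_acquisition(b$cfg, b$S, kin)
  a <- 5 * max(raw$y)
  flashed <- inject_flash_artifact(raw, c(0.05, 0.07), amplitude = a)
  expect_equal(length(flashed$meta$flash_windows), 1L)
  inw <- raw$time_s > 0.055 & raw$time_s < 0.065
  expect_true(all(flashed$y[inw, 1] - raw$y[inw, 1] >= a / 2))

  # amplitude 0 is the identity
  same <- inject_flash_artifact(raw, c(0.05, 0.07), amplitude = 0)
  expect_equal(same$y, raw$y)
  expect_error(inject_flash_artifact(raw, c(0.09, 0.2), 1), "outside")

  # demodulated deviation during the window is < 1 % of the amplitude
  cfg <- lockin_config(1e-3, 3, output_interval_s = 1e-4)
  ch <- demod_channels("dye", "D1", 3e4)
  d0 <- demodulate(raw, ch, cfg)
  d1 <- demodulate(flashed, ch, cfg)
  inw2 <- d0$time_s >= 0.05 & d0$time_s <= 0.07
  expect_lt(max(abs(d1$x[inw2, 1] - d0$x[inw2, 1])), 0.01 * a)
})

test_that("mixing artifact is proportional across detectors and croppable", {
  led <- boxcar_spectrum(460, 500)
  sp <- species("dye", excitation = boxcar_spectrum(450, 510),
                emission = boxcar_spectrum(520, 620))
  exch <- list(excitation_channel("c1", led, "485/20", 3e4))
  det <- list(detection_channel("D1", list("540/30")),
              detection_channel("D2", list("593LP")))
  cfg <- acquisition_config(exch, det, duration_s = 0.05, sim_rate_hz = 5e5)
  S <- build_coupling_tensor(list(sp), exch, det)
  raw <- simulate_acquisition(cfg, S, const_kin(0.05))
  mixed <- inject_mixing_artifact(raw, stop_time_s = 0.01, amplitude = 0.5,
                                  decay_s = 2e-3)
  g1 <- mixed$y[, 1] / raw$y[, 1]
  g2 <- mixed$y[, 2] / raw$y[, 2]
  expect_equal(g1, g2, tolerance = 1e-9)  # proportional on all detectors

  # cropping from the recorded window removes >= 99 % of the disturbance
  m <- mixed$meta$mixing[[1]]
  crop_end <- m$stop_time_s + 5 * m$decay_s  # 5 decay constants
  after <- raw$time_s > crop_end
  energy <- function(sel) sum((mixed$y[sel, 1] - raw$y[sel, 1])^2)
  expect_lt(energy(after) / energy(raw$time_s >= m$stop_time_s), 0.01)

  expect_equal(inject_mixing_artifact(raw, 0.01, 0, 1e-3)$y, raw$y)
})

test_that("dead time is dead volume over flow rate", {
  expect_equal(dead_time(36.6, 1), 0.0366)
  expect_equal(dead_time(36.6, 2), 0.0183)
  # halving the volume is equivalent to doubling the rate
  expect_equal(dead_time(18.3, 1), dead_time(36.6, 2))
  expect_error(dead_time(-1, 1), "positive")
  expect_error(dead_time(36.6, 0), "positive")
})

test_that("square-wave drive and soft saturation behave as documented", {
  exch <- excitation_channel("x", gaussian_band(490, 25), "485/20",
                             mod_freq_hz = 1e4, waveform = "square")
  t <- seq(0, 1e-3, by = 1e-6)
  I <- led_intensity(exch, t)
  expect_true(all(I %in% c(0, 1)))          # full-depth square wave
  expect_equal(mean(I), 0.5, tolerance = 0.01)
  # odd harmonic present in the square drive
  n <- length(t) - 1
  sp <- Mod(stats::fft(I[1:n] - mean(I[1:n])))
  fgrid <- (0:(n - 1)) / (n * 1e-6)
  expect_gt(sp[which.min(abs(fgrid - 3e4))], 0.1 * sp[which.min(abs(fgrid - 1e4))])

  # saturation compresses the peaks, Inf level is exactly linear
  b <- tiny_bench(freqs = 3e4, duration = 0.01, rate = 5e5)
  kin <- const_kin(0.01)
  lin <- simulate_acquisition(b$cfg, b$S, kin)
  b$cfg$saturation_level <- 0.8 * max(lin$y)
  satd <- simulate_acquisition(b$cfg, b$S, kin)
  expect_lt(max(satd$y), max(lin$y))
  expect_true(all(satd$y <= b$cfg$saturation_level + 1e-12))
})
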