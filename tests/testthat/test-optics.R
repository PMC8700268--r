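test_that("filter transmission matches the nominal passband", {
  wl <- default_wavelengths()
  bp <- filter_transmission("485/20", wl)
  expect_equal(eval_spectrum(bp, 485), 1, tolerance = 1e-9)
  expect_equal(eval_spectrum(bp, 300), 0)
  # raised-cosine edge crosses 0.5 exactly at the nominal half-width
  expect_equal(eval_spectrum(bp, 475), 0.5, tolerance = 1e-9)
  lp <- filter_transmission(filter_spec("longpass", cutoff_nm = 593,
                                        edge_softness_nm = 2), wl)
  expect_gte(eval_spectrum(lp, 650), 0.99)
  expect_equal(eval_spectrum(lp, 500), 0)
})

test_that("filter transmission stays within [0, 1] for random filters", {
  wl <- default_wavelengths()
  set.seed(11)
  for (i in 1:25) {
    f <- if (i %% 2 == 0) {
      filter_spec("bandpass", center_nm = runif(1, 320, 700),
                  fwhm_nm = runif(1, 5, 120),
                  edge_softness_nm = runif(1, 0, 10))
    } else {
      filter_spec("longpass", cutoff_nm = runif(1, 320, 700),
                  edge_softness_nm = runif(1, 0, 10))
    }
    v <- filter_transmission(f, wl)$values
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("vendor filter notation parses and bad input errors", {
  f <- parse_filter("379/34")
  expect_equal(f$center_nm, 379)
  expect_equal(f$fwhm_nm, 34)
  expect_equal(parse_filter("593LP")$cutoff_nm, 593)
  expect_error(parse_filter("blue"), "cannot parse")
  expect_error(filter_spec("bandpass", center_nm = 485, fwhm_nm = -3),
               "fwhm")
})

test_that("coupling coefficient equals the product of overlap integrals", {
  wl <- default_wavelengths()
  led <- boxcar_spectrum(400, 420)
  sp <- species("box",
                excitation = boxcar_spectrum(395, 430, 0.5),
                emission = boxcar_spectrum(500, 540, 0.8))
  exf <- filter_spec("bandpass", center_nm = 410, fwhm_nm = 10,
                     edge_softness_nm = 0)
  emf <- filter_spec("bandpass", center_nm = 520, fwhm_nm = 30,
                     edge_softness_nm = 0)
  exch <- excitation_channel("x", led, exf, 3e4, intensity = 2)
  det <- detection_channel("d", list(emf), gain = 1.5)

  # oracle: explicit product vectors, independent trapezoid rule
  ex_prod <- eval_spectrum(led, wl) * filter_transmission(exf, wl)$values *
    eval_spectrum(sp$excitation, wl)
  em_prod <- eval_spectrum(sp$emission, wl) * filter_transmission(emf, wl)$values
  expected <- 1 * 2 * 1.5 * trapz_oracle(wl, ex_prod) * trapz_oracle(wl, em_prod)
  expect_equal(coupling_coefficient(sp, exch, det), expected,
               tolerance = 1e-9)
})

test_that("coupling is bilinear in brightness and intensity and 0 for disjoint support", {
  led <- boxcar_spectrum(560, 575)
  sp <- species("uv", excitation = boxcar_spectrum(330, 420, 1),
                emission = boxcar_spectrum(450, 520, 1))
  exf <- filter_spec("bandpass", center_nm = 565, fwhm_nm = 19)
  det <- detection_channel("d", list("470/40"))
  exch <- excitation_channel("x", led, exf, 3e4)
  expect_equal(coupling_coefficient(sp, exch, det), 0)

  sp2 <- species("vis", excitation = boxcar_spectrum(470, 500),
                 emission = boxcar_spectrum(510, 560))
  exch2 <- excitation_channel("x", boxcar_spectrum(460, 500), "485/20", 3e4)
  det2 <- detection_channel("d", list("524/24"))
  c1 <- coupling_coefficient(sp2, exch2, det2)
  sp2b <- species("vis", excitation = sp2$excitation, emission = sp2$emission,
                  brightness = 2)
  expect_equal(coupling_coefficient(sp2b, exch2, det2), 2 * c1)
  exch2b <- excitation_channel("x", boxcar_spectrum(460, 500), "485/20", 3e4,
                               intensity = 3)
  expect_equal(coupling_coefficient(sp2, exch2b, det2), 3 * c1)
})

test_that("coupling tensor has the right shape, symmetry and detector contrast", {
  b <- bench_triple()
  probes <- unlist(lapply(c("Fura-2", "BCECF", "RhoVR", "Fluo-4"),
                          function(p) get_probe(p)$states),
                   recursive = FALSE)
  S <- build_coupling_tensor(probes, b$exch, b$det)
  expect_equal(dim(S), c(2L, 3L, length(probes)))
  expect_true(all(S >= 0))

  # permuting the species order permutes the s-axis identically
  perm <- rev(seq_along(probes))
  S2 <- build_coupling_tensor(probes[perm], b$exch, b$det)
  expect_equal(S2, S[, , perm])

  # the red-shifted voltage dye lands overwhelmingly on the long-wavelength
  # detector
  rho_d2 <- sum(S["D2", , "RhoVR"])
  rho_d1 <- sum(S["D1", , "RhoVR"])
  expect_gt(rho_d2, 10 * rho_d1)

  dup <- c(probes[1], probes[1])
  expect_error(build_coupling_tensor(dup, b$exch, b$det), "duplicate")
})

test_that("frequency plan separates the standard multiplexing set and flags collisions", {
  plan <- plan_frequencies(c(30.4e3, 37.3e3, 50e3), tau_s = 1e-3, order = 3,
                           sim_rate_hz = 1e6)
  expect_true(plan$pass)
  expect_lt(plan$worst_leakage_fraction, 0.001)  # < 0.1 %
  expect_equal(plan$noise_bandwidth_hz, 3 / (32 * 1e-3), tolerance = 1e-12)

  # 100 Hz apart vs a ~94 Hz noise bandwidth: flagged
  plan2 <- plan_frequencies(c(30.0e3, 30.1e3), tau_s = 1e-3, order = 3,
                            sim_rate_hz = 1e6)
  expect_false(plan2$pass)
  expect_true(any(grepl("noise bandwidth", plan2$issues)))

  plan3 <- plan_frequencies(c(30e3, 6e5), sim_rate_hz = 1e6)
  expect_false(plan3$pass)
  expect_true(any(grepl("Nyquist", plan3$issues)))
})

test_that("spectra validate their invariants", {
  expect_error(spectrum_nm(c(400, 400, 410), c(1, 1, 1)), "increasing")
  expect_error(spectrum_nm(c(400, 410), c(-1, 1)), "nonnegative")
  expect_error(spectrum_nm(c(400, 410), c(1.2, 1), transmission = TRUE),
               "exceed")
  s <- gaussian_band(500, 30)
  expect_equal(eval_spectrum(s, 2000), 0)  # outside the grid
  expect_error(species("bad", gaussian_band(600, 30), gaussian_band(500, 30)),
               "emission peak")
})
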