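# Multi-peak chemical-shift signal model: unit conversions, fat phasor,
# forward GRE signal, Nyquist echo spacing, protocol presets.

test_that("ppm-to-Hz conversion is linear in B0 with the Larmor constant", {
  expect_identical(ppm_to_hz(0, 3), 0)
  # direct arithmetic: -3.3e-6 * 42.577e6 Hz/T * 3 T
  expect_equal(ppm_to_hz(-3.3, 3), -3.3e-6 * 42.577e6 * 3)
  expect_equal(ppm_to_hz(-3.3, 7), 7 / 3 * ppm_to_hz(-3.3, 3))
  expect_error(ppm_to_hz(-3.3, -1))
})

test_that("shipped fat models match the published spectra and normalize", {
  fp <- fat_model("phantom")
  fi <- fat_model("invivo")
  expect_length(fp$shift_ppm, 9)
  expect_length(fi$shift_ppm, 8)
  expect_equal(sum(fp$rel_amp), 1, tolerance = 1e-3)
  expect_equal(sum(fi$rel_amp), 1, tolerance = 1e-3)
  expect_false(anyDuplicated(fp$shift_ppm) > 0)
  # dominant methylene peaks
  expect_equal(fp$shift_ppm[which.max(fp$rel_amp)], -3.51)
  expect_equal(fi$shift_ppm[which.max(fi$rel_amp)], -3.24)
  # amplitudes are renormalized on load even if the table drifted
  fm <- new_fat_model("x", c(-3.3, 0.6), c(2, 1))
  expect_equal(sum(fm$rel_amp), 1)
})

test_that("fat phasor equals the direct complex peak sum", {
  fp <- fat_model("phantom")
  expect_equal(fat_phasor(fp, 7, 0), 1 + 0i)
  # single peak at half the beat period is exactly opposed-phase
  sp <- single_peak_model(-3.3)
  half_beat <- 1 / (2 * abs(ppm_to_hz(-3.3, 3)))
  expect_equal(fat_phasor(sp, 3, half_beat), -1 + 0i, tolerance = 1e-12)
  # independent term-by-term summation oracle at 7 T, TE = 1.9 ms
  te <- 1.9e-3
  oracle <- sum(fp$rel_amp *
                  exp(1i * 2 * pi * fp$shift_ppm * 1e-6 * 42.577e6 * 7 * te))
  expect_equal(fat_phasor(fp, 7, te), oracle)
  expect_lte(Mod(fat_phasor(fp, 7, 1.23e-3)), 1 + 1e-12)
})

test_that("forward GRE signal matches the analytic voxel model", {
  proto <- protocol_preset("7T-highNSA")
  fi <- fat_model("invivo")
  # water only, no decay, no off-resonance: constant real vector
  s <- gre_signal(voxel_params(rho_w = 2), fi, proto)
  expect_equal(s, rep(2 + 0i, 6))
  # opposed-phase cancellation for equal water/fat single-peak voxel
  sp <- single_peak_model(-3.3)
  half_beat <- 1 / (2 * abs(ppm_to_hz(-3.3, 7)))
  po <- acquisition_protocol(7, te_list = c(half_beat, 2 * half_beat))
  s <- gre_signal(voxel_params(rho_w = 1, rho_f = 1), sp, po)
  expect_equal(Mod(s[1]), 0, tolerance = 1e-12)
  expect_equal(Mod(s[2]), 2, tolerance = 1e-12)
  # full model against an independent term-by-term oracle
  p <- voxel_params(1, 0.2, 0.5, -0.3, 40, 50)
  oracle <- sapply(proto$te, function(t) {
    cn <- sum(fi$rel_amp * exp(1i * 2 * pi * fi$shift_ppm * 1e-6 *
                                 42.577e6 * 7 * t))
    (1 * exp(0.2i) + 0.5 * exp(-0.3i) * cn) *
      exp(1i * 2 * pi * 40 * t) * exp(-50 * t)
  })
  expect_equal(gre_signal(p, fi, proto), oracle)
})

test_that("signal model invariants: decay, off-resonance factorization,
           phasor periodicity", {
  proto <- protocol_preset("3T-highNSA")
  fi <- fat_model("invivo")
  # pure exponential decay is non-increasing in TE
  s <- Mod(gre_signal(voxel_params(rho_w = 1, r2s = 80), fi, proto))
  expect_true(all(diff(s) < 0))
  # off-resonance enters as a pure elementwise phase factor
  p0 <- voxel_params(0.8, 0.1, 0.4, -0.2, 0, 60)
  pD <- voxel_params(0.8, 0.1, 0.4, -0.2, 135, 60)
  expect_equal(gre_signal(pD, fi, proto),
               gre_signal(p0, fi, proto) *
                 exp(1i * 2 * pi * 135 * proto$te))
  # single-peak phasor is periodic with the beat period
  sp <- single_peak_model(-3.3)
  beat <- 1 / abs(ppm_to_hz(-3.3, 3))
  te <- c(1.1e-3, 2.7e-3)
  expect_equal(fat_phasor(sp, 3, te + beat), fat_phasor(sp, 3, te),
               tolerance = 1e-9)
})

test_that("Nyquist echo spacing is ~1.2 ms at 3 T and ~0.5 ms at 7 T", {
  expect_equal(round(nyquist_dte(-3.3, 3) * 1e3, 1), 1.2)
  expect_equal(round(nyquist_dte(-3.3, 7) * 1e3, 1), 0.5)
  expect_equal(nyquist_dte(-3.3, 6), nyquist_dte(-3.3, 3) / 2)
  expect_error(nyquist_dte(0, 3))
})

test_that("acquisition protocols validate and presets carry the published
           echo times", {
  p <- acquisition_protocol(7, te1 = 1.9e-3, dte = 2.3e-3)
  expect_equal(p$te, 1.9e-3 + 2.3e-3 * 0:5)
  expect_error(acquisition_protocol(7, te_list = c(2e-3, 1e-3)))
  expect_error(acquisition_protocol(7, te1 = 1e-3, dte = 1e-3,
                                    readout_axis = "x",
                                    phase_encode_axis = "x"))
  te1 <- c("3T-lowNSA" = 2.2, "3T-highNSA" = 2.2, "7T-lowNSA" = 1.9,
           "7T-highNSA" = 1.9, "7T-shifted" = 2.2)
  dte <- c("3T-lowNSA" = 2.24, "3T-highNSA" = 3.2, "7T-lowNSA" = 2.0,
           "7T-highNSA" = 2.3, "7T-shifted" = 2.3)
  for (nm in names(te1)) {
    pr <- protocol_preset(nm)
    expect_equal(pr$te[1] * 1e3, te1[[nm]])
    expect_equal((pr$te[2] - pr$te[1]) * 1e3, dte[[nm]])
    expect_length(pr$te, 6)
  }
})

test_that("voxel parameters reject invalid magnitudes", {
  expect_error(voxel_params(-1))
  expect_error(voxel_params(1, r2s = -5))
  p <- voxel_params(0.6, 0, 0.4)
  expect_equal(p$rho_f / (p$rho_w + p$rho_f), 0.4)
})
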