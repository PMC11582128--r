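# Dual-echo B0 mapping, demodulation, and correction-mode comparison.

test_that("dual-echo B0 maps recover uniform offsets and wrap beyond the
           aliasing band", {
  fm <- fat_model("invivo")
  te <- c(2.04e-3, 4.08e-3)
  ph <- make_vial_phantom(grid_size = 24)
  proto <- acquisition_protocol(7, te_list = te)
  # identical echoes -> zero offset
  ser <- simulate_acquisition(ph, fm, proto)
  b0 <- dual_echo_b0_map(echo_image(ser, 1), echo_image(ser, 1),
                         te[1], te[2])
  expect_true(all(b0$delta_f == 0))
  # uniform 100 Hz offset comes back exactly on a water-only object (fat
  # voxels pick up a small multi-peak phase residue even at in-phase TEs)
  phw <- make_vial_phantom(vff = 0, grid_size = 24)
  phw$b0[] <- 100
  serw <- simulate_acquisition(phw, fm, proto)
  b1 <- dual_echo_b0_map(echo_image(serw, 1), echo_image(serw, 2),
                         te[1], te[2])
  expect_equal(range(b1$delta_f[b1$valid_mask]), c(100, 100),
               tolerance = 1e-6)
  ph$b0[] <- 100
  ser <- simulate_acquisition(ph, fm, proto)
  b1f <- dual_echo_b0_map(echo_image(ser, 1), echo_image(ser, 2),
                          te[1], te[2])
  # fat-containing voxels keep a residue from the non-real multi-peak
  # phasor; bounded well inside the aliasing band
  expect_lt(max(abs(b1f$delta_f[b1f$valid_mask] - 100)), 30)
  expect_equal(b1$aliasing_hz, 1 / (2 * diff(te)), tolerance = 1e-12)
  # beyond the band: wraps by 1/dTE per the modular-arithmetic oracle
  ph$b0[] <- 300
  ser <- simulate_acquisition(ph, fm, proto)
  b2 <- dual_echo_b0_map(echo_image(ser, 1), echo_image(ser, 2),
                         te[1], te[2])
  wrapped <- 300 - 1 / diff(te)   # 300 - 490.2 = -190.2 Hz
  expect_equal(stats::median(b2$delta_f[b2$valid_mask]), wrapped,
               tolerance = 1e-3)
  # low-magnitude voxels are invalid, not NaN
  expect_true(all(is.finite(b2$delta_f)))
  expect_true(all(!b2$valid_mask[ph$labels == 0L]))
})

test_that("off-in-phase echo pairs trigger the in-phase warning", {
  ph <- make_vial_phantom(grid_size = 16)
  fm <- fat_model("invivo")
  te <- c(1.5e-3, 3.0e-3)  # opposed-ish at 7 T for the dominant peak
  ser <- simulate_acquisition(ph, fm, acquisition_protocol(7, te_list = te))
  expect_warning(dual_echo_b0_map(echo_image(ser, 1), echo_image(ser, 2),
                                  te[1], te[2], fat_model = fm, b0 = 7),
                 "in-phase")
})

test_that("demodulation is an exact involution that preserves magnitudes", {
  fm <- fat_model("invivo")
  ph <- make_calf_phantom(grid_size = 24)
  ph <- make_field_map(ph, 120, 40)
  ser <- simulate_acquisition(ph, fm, protocol_preset("7T-highNSA"),
                              noise_sd = 0.01, seed = 8)
  zero_map <- structure(list(delta_f = matrix(0, 24, 24),
                             valid_mask = matrix(TRUE, 24, 24),
                             te_pair = c(2.04e-3, 4.08e-3),
                             aliasing_hz = 245.1), class = "b0_map")
  expect_equal(demodulate(ser, zero_map)$data, ser$data)
  truth_map <- zero_map
  truth_map$delta_f <- ph$b0
  dem <- demodulate(ser, truth_map)
  expect_equal(Mod(dem$data), Mod(ser$data), tolerance = 1e-12)
  neg <- truth_map
  neg$delta_f <- -ph$b0
  expect_equal(demodulate(dem, neg)$data, ser$data, tolerance = 1e-12)
  small <- structure(list(delta_f = matrix(0, 8, 8),
                          valid_mask = matrix(TRUE, 8, 8),
                          te_pair = c(2.04e-3, 4.08e-3),
                          aliasing_hz = 245.1), class = "b0_map")
  expect_error(demodulate(ser, small), "match")
})

test_that("demodulating with the true field re-centers the estimated field
           map and shrinks its range", {
  fm <- fat_model("phantom")
  ph <- make_vial_phantom(grid_size = 32)
  ph <- make_field_map(ph, 150, 0)
  ser <- simulate_acquisition(ph, fm, protocol_preset("7T-highNSA"),
                              noise_sd = 0)
  truth_map <- structure(list(delta_f = ph$b0,
                              valid_mask = matrix(TRUE, 32, 32),
                              te_pair = c(2.04e-3, 4.08e-3),
                              aliasing_hz = 245.1), class = "b0_map")
  cfg <- fws_config(fat_model = fm)
  raw <- separate(ser, cfg)
  dem <- separate(demodulate(ser, truth_map), cfg)
  step <- diff(cfg$offres_grid[1:2])
  expect_lte(max(abs(dem$field_map[dem$mask])), step)
  expect_lt(diff(range(dem$field_map[dem$mask])),
            diff(range(raw$field_map[raw$mask])))
})

test_that("a clean zero-field acquisition shows no swaps under any
           correction mode", {
  ph <- make_calf_phantom(grid_size = 24)
  cfg <- fws_config(fat_model = fat_model("invivo"),
                    offres_grid = seq(-300, 300, length.out = 101),
                    r2s_grid = seq(0, 400, length.out = 21))
  tab <- suppressWarnings(
    compare_protocols(ph, seeds = 1, noise_sd = 0, eddy_amplitude = 0,
                      eddy_gradient = 0, config = cfg))
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$swap_rate == 0))
  # TE-shift modes run the shifted protocol, others the base protocol
  expect_setequal(tab$protocol[tab$mode %in% c("te-shift", "both")],
                  "shifted")
})
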