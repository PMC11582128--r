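# Digital phantoms and simulated acquisitions.

test_that("vial phantom carries the requested volume fat fractions
           exactly", {
  ph <- make_vial_phantom()
  vt <- c(0.05, 0.10, 0.25, 0.50, 0.75, 1.00)
  for (k in 1:6) {
    m <- ph$labels == ph$label_names[[paste0("vial", k)]]
    expect_gt(sum(m), 0)
    expect_equal(unique(ph$pdff[m]), vt[k])
  }
  expect_true(all(ph$rho[ph$labels == 0L] == 0))
  expect_true(all(ph$pdff >= 0 & ph$pdff <= 1))
  # a zero-VFF vial is indistinguishable from the bath in pdff truth
  ph0 <- make_vial_phantom(vff = 0)
  expect_true(all(ph0$pdff == 0))
})

test_that("vial rasterization matches the analytic disk area to within the
           perimeter", {
  ph <- make_vial_phantom(grid_size = 96, vial_radius = 0.10)
  r <- 0.10 * 96
  area <- pi * r^2
  perim <- 2 * pi * r
  for (k in 1:6) {
    n_vox <- sum(ph$labels == ph$label_names[[paste0("vial", k)]])
    expect_lt(abs(n_vox - area), perim)
  }
})

test_that("overlapping vial geometry is rejected", {
  expect_error(make_vial_phantom(vff = rep(0.5, 10), grid_size = 48,
                                 ring_radius = 0.15, vial_radius = 0.12),
               "overlap")
})

test_that("calf phantom has the requested regional PDFF truth and
           fat-ring enclosure", {
  ph <- make_calf_phantom()
  for (nm in c("ANT", "SOL", "GM")) {
    expect_equal(mean(ph$pdff[ph$labels == ph$label_names[[nm]]]), 0.03)
  }
  expect_equal(mean(ph$pdff[ph$labels == ph$label_names[["fat_ring"]]]),
               0.90)
  expect_equal(mean(ph$pdff[ph$labels == ph$label_names[["marrow"]]]),
               0.90)
  expect_lt(max(ph$rho[ph$labels == ph$label_names[["bone"]]]), 0.1)
  # enclosure oracle: along every row and column that contains muscle, the
  # outermost nonbackground voxels are subcutaneous ring
  lab <- ph$labels
  muscle_rows <- which(apply(lab, 1, function(r) any(r %in% 1:3)))
  for (i in muscle_rows) {
    nz <- which(lab[i, ] > 0L)
    expect_identical(lab[i, min(nz)], 4L)
    expect_identical(lab[i, max(nz)], 4L)
  }
})

test_that("field maps honor amplitude bounds and polynomial smoothness", {
  ph <- make_calf_phantom()
  ph0 <- make_field_map(ph, 0, 0)
  expect_true(all(ph0$b0 == 0))
  phf <- make_field_map(ph, smooth_amplitude = 120,
                        local_gradient_amplitude = 80)
  expect_lte(max(abs(phf$b0)), 120 + 80 + 1e-9)
  # quadratic polynomial: discrete 5-point Laplacian is spatially constant
  sm <- phf$b0_components$smooth
  n <- nrow(sm)
  lap <- sm[2:(n - 1), 2:(n - 1)] * -4 + sm[1:(n - 2), 2:(n - 1)] +
    sm[3:n, 2:(n - 1)] + sm[2:(n - 1), 1:(n - 2)] + sm[2:(n - 1), 3:n]
  expect_lt(diff(range(lap)), 1e-9 * max(abs(sm)))
})

test_that("eddy-current phase ramps apply, invert, and span the FOV as
           requested", {
  ph <- make_vial_phantom(grid_size = 32)
  fm <- fat_model("phantom")
  ser <- simulate_acquisition(ph, fm, protocol_preset("7T-highNSA"))
  expect_equal(apply_eddy_phase(ser, 0, 0)$data, ser$data)
  # applying a ramp and its negation restores the data
  s1 <- apply_eddy_phase(ser, 0.4, 0.07)
  s2 <- apply_eddy_phase(s1, -0.4, -0.07)
  expect_equal(s2$data, ser$data, tolerance = 1e-12)
  # a ramp of pi across the FOV gives antipodal phase at opposite edges:
  # the imposed extra phase at row 32 minus row 1 is pi (noisy series so
  # edge voxels carry nonzero signal)
  sern <- simulate_acquisition(ph, fm, protocol_preset("7T-highNSA"),
                               noise_sd = 0.1, seed = 5)
  g <- pi / 31
  s3 <- apply_eddy_phase(sern, 0, g)
  extra <- (s3$data[, 16, 1] * Conj(sern$data[, 16, 1]))
  rel <- extra[32] * Conj(extra[1])
  expect_equal(abs(Arg(rel)), pi, tolerance = 1e-9)
  # first-echo-only mode leaves echoes 2..N untouched
  expect_equal(s1$data[, , 2:6], ser$data[, , 2:6])
  # all-echo mode decays the ramp across the echo train
  s4 <- apply_eddy_phase(ser, 0.4, 0, mode = "all-echoes-linear",
                         decay_tau = 2e-3)
  ph2 <- Arg(s4$data[16, 16, 2] * Conj(ser$data[16, 16, 2]))
  expect_equal(ph2, 0.4 * exp(-(ser$protocol$te[2] - ser$protocol$te[1]) /
                                2e-3), tolerance = 1e-9)
})

test_that("simulated noise is reproducible, correctly scaled, and
           independent across seeds", {
  ph <- make_vial_phantom(grid_size = 180)
  fm <- fat_model("phantom")
  proto <- protocol_preset("7T-highNSA")
  a <- simulate_acquisition(ph, fm, proto, noise_sd = 0.03, seed = 21)
  b <- simulate_acquisition(ph, fm, proto, noise_sd = 0.03, seed = 21)
  expect_identical(a$data, b$data)
  bg <- ph$labels == 0L
  expect_gt(sum(bg), 1e4)
  # pooled real/imag SD over background voxels within 2%
  noise <- c(Re(a$data[, , 1][bg]), Im(a$data[, , 1][bg]),
             Re(a$data[, , 4][bg]), Im(a$data[, , 4][bg]))
  expect_equal(stats::sd(noise), 0.03, tolerance = 0.02)
  cc <- simulate_acquisition(ph, fm, proto, noise_sd = 0.03, seed = 22)
  expect_lt(abs(stats::cor(Re(a$data[, , 1][bg]), Re(cc$data[, , 1][bg]))),
            0.05)
})
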