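test_that("closed-form wall shear matches hand values and rejects bad input", {
  expect_equal(poiseuille_wall_shear(1.0, 0.01, 0.0032, 2), 0.64)
  expect_error(poiseuille_wall_shear(0, 0.01, 0.0032, 2), "domain error")
  expect_error(poiseuille_wall_shear(1, -0.01, 0.0032, 2), "domain error")
})

test_that("closed-form KE density matches the analytic integrals", {
  # parabolic: g(2) = 1/3
  expect_equal(powerlaw_mean_ke_density(1.0, 1060, 2), 1060 / 6)
  # plug-flow limit g -> 1
  expect_equal(powerlaw_mean_ke_density(1.0, 1060, 1e6), 530, tolerance = 1e-4)
  expect_equal(powerlaw_mean_ke_density(1.53, 1060, 2),
               0.5 * 1060 * 1.53^2 / 3)
  expect_error(powerlaw_mean_ke_density(1, 1060, 0), "domain error")
})

test_that("calibration inverts the closed forms", {
  cfg <- test_config()
  # recover known (vmax, n) from their own forward values
  fwd_wss <- poiseuille_wall_shear(1, 0.01, cfg$mu, 2)
  fwd_ke <- powerlaw_mean_ke_density(1, cfg$rho, 2)
  cal <- calibrate_segment(fwd_wss, fwd_ke, 0.01, cfg)
  expect_equal(cal$vmax, 1, tolerance = 1e-6)
  expect_equal(cal$n, 2, tolerance = 1e-6)

  # published aortic column: n ~ 1.53, vmax ~ 1.86 m/s, and the pair
  # reproduces the WSS target through the forward oracle
  cal2 <- calibrate_segment(0.73, 480.8, 0.0125, cfg)
  expect_equal(cal2$n, 1.53, tolerance = 0.01)
  expect_equal(cal2$vmax, 1.86, tolerance = 0.01)
  expect_equal(poiseuille_wall_shear(cal2$vmax, 0.0125, cfg$mu, cal2$n),
               0.73, tolerance = 1e-6)
  expect_equal(powerlaw_mean_ke_density(cal2$vmax, cfg$rho, cal2$n),
               480.8, tolerance = 1e-4)

  expect_error(calibrate_segment(1000, 0.001, 0.0125, cfg),
               "infeasible target")
})

test_that("uncorrupted phantom equals the analytic profile at voxel centres", {
  ph <- clean_parabolic()
  sp <- ph$spec
  geo <- hemoflow4d:::tube_geometry(sp)
  expected <- ifelse(geo$r <= sp$radius, 1 - (geo$r / sp$radius)^2, 0)
  for (c in 1:3) {
    expect_equal(ph$field$data[, , , 6, c], expected * geo$u[c])
  }
  # speeds outside the lumen are exactly zero
  expect_true(all(ph$field$data[, , , , 1][!ph$masks$lumen] == 0))
})

test_that("phantom generation is deterministic and truth ignores noise", {
  spec <- phantom_spec(radius = 10, profile_exponent = 2,
                       vmax_waveform = systolic_waveform(24, 2:10),
                       noise_frac = 0.02, seed = 42)
  a <- make_tube_phantom(spec)
  b <- make_tube_phantom(spec)
  expect_identical(a$field$data, b$field$data)
  spec2 <- phantom_spec(radius = 10, profile_exponent = 2,
                        vmax_waveform = systolic_waveform(24, 2:10),
                        noise_frac = 0.02, seed = 43)
  c <- make_tube_phantom(spec2)
  expect_false(identical(a$field$data, c$field$data))
  expect_identical(a$truth, c$truth)
})

test_that("truth records follow the closed forms and the waveform peak", {
  wf <- numeric(24)
  wf[2:9] <- sin(pi * (0:7) / 7)^2 * 1.5
  wf[5] <- 1.5    # force the peak at frame 5
  spec <- phantom_spec(radius = 10, profile_exponent = 2, vmax_waveform = wf,
                       noise_frac = 0, seed = 1)
  ph <- make_tube_phantom(spec)
  expect_identical(ph$truth$peak_systole_frame_true, 5L)
  expect_equal(ph$truth$peak_velocity_true, 1.5)
  expect_equal(ph$truth$wss_peak_true, 0.0032 * 2 * 1.5 / 0.01)
  expect_equal(ph$truth$ke_peak_true, 0.5 * 1060 * 1.5^2 / 3)
  dt <- 1000 / 24 / 1000
  expect_equal(ph$truth$stroke_volume_true,
               sum(pi * 100 * wf * 2 / 4) * dt)
})

test_that("corruptions compose as noise, then offset, then wrap", {
  base <- phantom_spec(radius = 10, profile_exponent = 2,
                       vmax_waveform = 1.8 * systolic_waveform(24, 2:10),
                       venc = 1.5, noise_frac = 0, seed = 7)
  clean <- make_tube_phantom(base)
  wrapped <- make_tube_phantom(
    phantom_spec(radius = 10, profile_exponent = 2,
                 vmax_waveform = 1.8 * systolic_waveform(24, 2:10),
                 venc = 1.5, alias = TRUE, noise_frac = 0, seed = 7))
  # wrap puts everything inside [-venc, venc); beyond-venc truth wraps down
  expect_true(all(abs(wrapped$field$data) <= 1.5))
  over <- clean$field$data > 1.5
  expect_true(any(over))
  expect_equal(wrapped$field$data[over], clean$field$data[over] - 2 * 1.5)
  # offsets shift the static margin uniformly (constant term)
  off <- make_tube_phantom(
    phantom_spec(radius = 10, profile_exponent = 2,
                 vmax_waveform = 1.8 * systolic_waveform(24, 2:10),
                 venc = 1.5, noise_frac = 0, seed = 7,
                 offset_coeffs = cbind(c(0.05, 0, 0), matrix(0, 3, 9))))
  st <- off$masks$static_tissue
  expect_equal(unique(round(off$field$data[, , , 1, 1][st], 12)), 0.05)
})

test_that("under-resolved tubes are rejected", {
  expect_error(phantom_spec(radius = 5), "resolution error")
})
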