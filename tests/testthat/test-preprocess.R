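series_field <- function(series, venc) {
  # a 2x2x2 field whose z-component follows `series` at every voxel
  data <- array(0, c(2, 2, 2, length(series), 3))
  for (t in seq_along(series)) data[, , , t, 3] <- series[t]
  velocity_field(data, c(1, 1, 1), frame_duration = 50, venc = venc)
}

test_that("anti-aliasing shifts wrapped samples by the jump-minimising multiple", {
  f <- series_field(c(0.2, 1.4, -1.2, 1.3), venc = 1.5)
  out <- unalias_velocity(f)
  expect_equal(out$data[1, 1, 1, , 3], c(0.2, 1.4, 1.8, 1.3))
  expect_identical(attr(out, "n_unwrapped"), 8L)  # 8 voxels, one frame each
})

test_that("anti-aliasing leaves consistent series alone and is idempotent", {
  f <- series_field(c(0.2, 1.0, -0.2, -1.0), venc = 1.5)
  out <- unalias_velocity(f)
  expect_identical(out$data, f$data)

  ph <- make_tube_phantom(
    phantom_spec(radius = 10, profile_exponent = 2,
                 vmax_waveform = 1.8 * systolic_waveform(24, 2:10),
                 venc = 1.5, alias = TRUE, noise_frac = 0, seed = 2))
  once <- unalias_velocity(ph$field)
  twice <- unalias_velocity(once)
  expect_identical(twice$data, once$data)
})

test_that("polynomial offsets in the model span are removed to 1e-6 m/s", {
  cfg <- test_config()
  wf <- systolic_waveform(24, 2:10)
  clean <- make_tube_phantom(
    phantom_spec(radius = 10, profile_exponent = 2, vmax_waveform = wf,
                 noise_frac = 0, seed = 3))
  cases <- list(
    constant = cbind(rep(0.05, 3), matrix(0, 3, 9)),
    linear_x = cbind(0, c(0.05, 0, 0), matrix(0, 3, 8)),
    zero = matrix(0, 3, 10)
  )
  for (nm in names(cases)) {
    ph <- make_tube_phantom(
      phantom_spec(radius = 10, profile_exponent = 2, vmax_waveform = wf,
                   noise_frac = 0, seed = 3, offset_coeffs = cases[[nm]]))
    fixed <- correct_background_offset(ph$field, ph$masks$static_tissue, cfg)
    expect_lt(max(abs(fixed$data - clean$field$data)), 1e-6)
  }
})

test_that("rank-deficient static sets fall back to a constant fit", {
  data <- array(0.02, c(6, 6, 6, 4, 3))
  f <- velocity_field(data, c(1, 1, 1), 50, 2)
  coplanar <- array(FALSE, c(6, 6, 6))
  coplanar[, , 3] <- TRUE            # a single slice: z terms unidentifiable
  expect_warning(out <- correct_background_offset(f, coplanar, test_config()),
                 "rank-deficient")
  expect_lt(max(abs(out$data)), 1e-12)
})

test_that("static-tissue detection separates margin from lumen", {
  cfg <- test_config()
  ph <- make_tube_phantom(
    phantom_spec(radius = 10, profile_exponent = 2,
                 vmax_waveform = 1.5 * systolic_waveform(24, 2:10),
                 noise_frac = 0, seed = 4))
  st <- detect_static_tissue(ph$field, cfg)
  expect_true(all(st[ph$masks$static_tissue]))
  # lumen voxels moving at peak must never be classified static
  core <- ph$field$data[, , , 6, 3] > 0.5
  expect_true(!any(st[core]))
})

test_that("pure noise at half venc leaves (almost) no static voxels", {
  set.seed(9)
  data <- array(stats::rnorm(6 * 6 * 6 * 8 * 3, sd = 1.0), c(6, 6, 6, 8, 3))
  f <- velocity_field(data, c(1, 1, 1), 50, venc = 2)
  suppressWarnings(st <- detect_static_tissue(f, test_config()))
  expect_lt(mean(st), 0.01)
})

test_that("PC-MRA is the time average of magnitude times speed", {
  f <- per_frame_speed_field(c(0.5, 1.0))
  mag <- magnitude_series(array(100, c(6, 6, 6, 2)))
  pc <- compute_pcmra(mag, f)
  expect_equal(pc$data, array(75, c(6, 6, 6)))

  z <- uniform_field(c(0, 0, 0), dim = c(6, 6, 6))
  pcz <- compute_pcmra(magnitude_series(array(100, c(6, 6, 6, 2))), z)
  expect_true(all(pcz$data == 0))

  # commutes with frame reordering
  f2 <- per_frame_speed_field(c(1.0, 0.5))
  pc2 <- compute_pcmra(mag, f2)
  expect_equal(pc2$data, pc$data)

  expect_error(compute_pcmra(magnitude_series(array(1, c(5, 6, 6, 2))), f),
               "do not match")
})

test_that("phantom PC-MRA lights the lumen far above background", {
  ph <- make_tube_phantom(
    phantom_spec(radius = 10, profile_exponent = 2,
                 vmax_waveform = 1.5 * systolic_waveform(24, 2:10),
                 noise_frac = 0.02, seed = 5))
  pc <- compute_pcmra(ph$magnitude, ph$field)
  lumen <- ph$masks$lumen
  expect_gt(mean(pc$data[lumen]), 10 * mean(pc$data[!lumen]))
})

test_that("offset correction restores the clean phantom's PC-MRA", {
  cfg <- test_config()
  wf <- 1.5 * systolic_waveform(24, 2:10)
  clean <- make_tube_phantom(
    phantom_spec(radius = 10, profile_exponent = 2, vmax_waveform = wf,
                 noise_frac = 0, seed = 6))
  crpt <- make_tube_phantom(
    phantom_spec(radius = 10, profile_exponent = 2, vmax_waveform = wf,
                 noise_frac = 0, seed = 6,
                 offset_coeffs = cbind(rep(0.04, 3), matrix(0, 3, 9))))
  pc_clean <- compute_pcmra(clean$magnitude, clean$field)
  # the uncorrected PC-MRA is visibly wrong in the static margin
  pc_bad <- compute_pcmra(crpt$magnitude, crpt$field)
  st <- crpt$masks$static_tissue
  expect_gt(mean(pc_bad$data[st]), 1)
  pp <- preprocess_field(crpt$field, cfg, static_mask = st)
  pc_fixed <- compute_pcmra(crpt$magnitude, pp$field)
  expect_lt(max(abs(pc_fixed$data - pc_clean$data)), 1e-6)
})
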