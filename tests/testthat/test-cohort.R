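zero_sd_row <- function() {
  tg <- reference_group_targets()
  row <- tg[tg$group == "isolated_myectomy", ]
  row[grep("_sd$", names(row))] <- 0
  row
}

test_that("zero-SD cohorts have truths equal to the group means", {
  coh <- make_cohort(zero_sd_row(), n_subjects = 3, seed = 5,
                     noise_frac = 0, offsets = FALSE, alias = FALSE)
  tt <- coh$target_table
  expect_true(all(tt$wss_aorta == 0.73))
  expect_true(all(tt$vpeak_lvot == 1.63))
  for (s in coh$subjects) {
    expect_equal(s$segments$aorta$truth$wss_peak_true, 0.73,
                 tolerance = 1e-6)
    expect_equal(s$segments$aorta$truth$ke_peak_true, 480.8,
                 tolerance = 1e-6)
    expect_equal(s$segments$lvot$truth$peak_velocity_true, 1.63,
                 tolerance = 1e-6)
    expect_equal(s$segments$lvot$truth$ke_peak_true, 314.2,
                 tolerance = 1e-6)
    expect_equal(s$segments$aorta$truth$stroke_volume_true, 63,
                 tolerance = 1e-6)
    expect_equal(s$segments$lvot$truth$stroke_volume_true, 84,
                 tolerance = 1e-6)
  }
})

test_that("drawn targets are moment-matched to the printed mean and SD", {
  tg <- reference_group_targets()
  row <- tg[tg$group == "isolated_myectomy", ]
  coh <- make_cohort(row, n_subjects = 3, seed = 7, noise_frac = 0,
                     offsets = FALSE, alias = FALSE)
  tt <- coh$target_table
  expect_equal(mean(tt$wss_aorta), 0.73)
  expect_equal(stats::sd(tt$wss_aorta), 0.1)
  expect_equal(mean(tt$vpeak_lvot), 1.63)
  expect_equal(stats::sd(tt$vpeak_lvot), 0.3)
  expect_equal(mean(tt$ke_lvot), 314.2)
  expect_equal(mean(tt$av_forward), 63)
  # per-subject truths match the drawn targets (calibration is exact)
  for (i in 1:3) {
    s <- coh$subjects[[i]]
    expect_equal(s$segments$aorta$truth$wss_peak_true, tt$wss_aorta[i],
                 tolerance = 1e-6)
    expect_equal(s$segments$lvot$truth$ke_peak_true, tt$ke_lvot[i],
                 tolerance = 1e-6)
    expect_equal(s$segments$aorta$truth$stroke_volume_true, tt$av_forward[i],
                 tolerance = 1e-6)
    expect_equal(s$segments$lvot$truth$stroke_volume_true, tt$mv_forward[i],
                 tolerance = 1e-6)
  }
})

test_that("healthy-control cohorts carry the 1.25 m/s peak-velocity truth", {
  tg <- reference_group_targets()
  row <- tg[tg$group == "healthy_control", ]
  coh <- make_cohort(row, n_subjects = 3, seed = 9, segments = "lvot")
  truths <- vapply(coh$subjects,
                   function(s) s$segments$lvot$truth$peak_velocity_true,
                   numeric(1))
  expect_equal(mean(truths), 1.25, tolerance = 1e-6)
  expect_equal(stats::sd(truths), 0)   # printed SD is 0
})

test_that("cohorts are reproducible for a fixed seed", {
  row <- reference_group_targets()[1, ]
  a <- make_cohort(row, n_subjects = 2, seed = 11, segments = "aorta")
  b <- make_cohort(row, n_subjects = 2, seed = 11, segments = "aorta")
  expect_identical(a$target_table, b$target_table)
  expect_identical(a$subjects[[2]]$segments$aorta$field$data,
                   b$subjects[[2]]$segments$aorta$field$data)
  c <- make_cohort(row, n_subjects = 2, seed = 12, segments = "aorta")
  expect_false(identical(a$target_table, c$target_table))
})

test_that("the healthy aortic column triggers the radius adaptation", {
  cfg <- test_config()
  # at the default 12.5 mm radius these targets admit no exponent >= 1
  expect_error(calibrate_segment(0.47, 345.4, 0.0125, cfg), "infeasible")
  r <- hemoflow4d:::feasible_radius(0.47, 345.4, 12.5, cfg)
  expect_gt(r, 12.5)
  cal <- calibrate_segment(0.47, 345.4, r / 1000, cfg)
  expect_gte(cal$n, 1)
  expect_equal(poiseuille_wall_shear(cal$vmax, r / 1000, cfg$mu, cal$n),
               0.47, tolerance = 1e-6)
})

test_that("waveforms hit stroke-volume targets across the study range", {
  for (sv in c(63, 74, 84, 90)) {
    wf <- hemoflow4d:::waveform_for_sv(sv, vmax = 1.63, n = 1.35,
                                       radius = 9.4)
    dt <- 1000 / 24 / 1000
    got <- sum(pi * 9.4^2 * wf * 1.35 / 3.35) * dt
    expect_equal(got, sv, tolerance = 1e-6)
    expect_equal(max(wf[1:12]), 1.63, tolerance = 1e-9)  # systolic peak kept
  }
  expect_error(hemoflow4d:::waveform_for_sv(1e4, 1.63, 1.35, 9.4),
               "infeasible stroke-volume")
})

test_that("impossible group targets fail with diagnostics", {
  row <- reference_group_targets()[1, ]
  row$ke_lvot <- 5000          # no exponent can carry this KE at 1.63 m/s
  row$ke_lvot_sd <- 0
  expect_error(make_cohort(row, n_subjects = 3, seed = 1, segments = "lvot"),
               "infeasible")
})
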