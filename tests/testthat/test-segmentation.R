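test_that("threshold keeps exactly the bright voxels of a two-valued volume", {
  vol <- array(0, c(8, 8, 8))
  vol[3:5, 3:5, 3:5] <- 100
  pc <- structure(list(data = vol, spacing = c(1, 1, 1)), class = "pcmra")
  seg <- segment_threshold(pc, 0.3)
  expect_identical(seg, vol == 100)
})

test_that("threshold masks shrink monotonically in the fraction", {
  ph <- clean_parabolic()
  pc <- compute_pcmra(ph$magnitude, ph$field)
  lo <- segment_threshold(pc, 0.5)
  hi <- segment_threshold(pc, 0.999)
  expect_true(all(lo[hi]))          # hi subset of lo
  expect_lt(sum(hi), sum(lo))
})

test_that("blunt-profile phantoms segment to the lumen with Dice >= 0.9", {
  ph <- make_tube_phantom(
    phantom_spec(radius = 10, profile_exponent = 8,
                 vmax_waveform = rep(1, 24), noise_frac = 0.02, seed = 3))
  pc <- compute_pcmra(ph$magnitude, ph$field)
  seg <- segment_threshold(pc, 0.5)
  dice <- 2 * sum(seg & ph$masks$lumen) / (sum(seg) + sum(ph$masks$lumen))
  expect_gte(dice, 0.9)
})

test_that("cylinder surface area approaches the analytic value", {
  cyl <- cylinder_mask(radius = 10, length = 40)
  surf <- extract_wall_surface(cyl$mask, cyl$spacing)
  lateral <- 2 * pi * cyl$radius * cyl$length
  caps <- 2 * pi * cyl$radius^2
  expect_equal(sum(surf$area_weights), lateral + caps,
               tolerance = 0.1)
  # open tube (flow continues through the ends): lateral wall only
  flow <- cyl$mask
  flow[, , ] <- rep(flow[, , which(cyl$in_z)[1]], dim(cyl$mask)[3])
  surf_open <- extract_wall_surface(cyl$mask, cyl$spacing, flow_mask = flow)
  expect_equal(sum(surf_open$area_weights), lateral, tolerance = 0.1)
})

test_that("area stays accurate and normals converge under refinement", {
  angle_err <- function(fct) {
    sp <- c(2.4, 2.4, 2.5) / fct
    cyl <- cylinder_mask(10, 40, spacing = sp)
    surf <- extract_wall_surface(cyl$mask, cyl$spacing,
                                 smooth_sigma = 2.8 / fct)
    true_area <- 2 * pi * 10 * cyl$length + 2 * pi * 100
    expect_equal(sum(surf$area_weights), true_area, tolerance = 0.02)
    ctr <- ((dim(cyl$mask)[1:2] - 1) / 2) * sp[1:2]
    lat <- abs(surf$inward_normals[, 3]) < 0.3
    rad <- cbind(surf$points[lat, 1] - ctr[1],
                 surf$points[lat, 2] - ctr[2], 0)
    rad <- rad / sqrt(rowSums(rad^2))
    mean(acos(pmin(1, -rowSums(rad * surf$inward_normals[lat, ]))))
  }
  errs <- vapply(c(1, 2, 4), angle_err, numeric(1))
  expect_true(all(diff(errs) < 0))   # strictly better at every refinement
})

test_that("surface invariants hold: unit normals, positive weights, closeness", {
  ph <- clean_parabolic()
  surf <- extract_wall_surface(ph$masks$aorta, ph$field$spacing,
                               flow_mask = ph$masks$lumen)
  expect_lt(max(abs(sqrt(rowSums(surf$inward_normals^2)) - 1)), 1e-6)
  expect_true(all(surf$area_weights > 0))
})

test_that("a single voxel yields a closed box surface", {
  mask <- array(FALSE, c(7, 7, 7))
  mask[4, 4, 4] <- TRUE
  surf <- extract_wall_surface(mask, c(2, 2, 2))
  expect_identical(nrow(surf$points), 6L)
  expect_equal(sum(surf$area_weights), 6 * 4, tolerance = 0.01)
  # inward normals point back toward the voxel centre
  ctr <- matrix(c(3, 3, 3) * 2, 6, 3, byrow = TRUE)
  to_ctr <- ctr - surf$points
  expect_true(all(rowSums(to_ctr * surf$inward_normals) > 0))
})

test_that("sphere normals point inward everywhere", {
  d <- c(13, 13, 13)
  ctr <- (d - 1) / 2 * 2
  xs <- (seq_len(d[1]) - 1) * 2
  r <- sqrt(outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, "+"),
                  (xs - ctr[3])^2, "+"))
  mask <- array(r <= 8, d)
  surf <- extract_wall_surface(mask, c(2, 2, 2))
  radial <- sweep(surf$points, 2, ctr)          # outward direction
  expect_true(all(rowSums(radial * surf$inward_normals) < 0))
})

test_that("masks touching the border are rejected with advice to pad", {
  mask <- array(TRUE, c(4, 4, 4))
  expect_error(extract_wall_surface(mask, c(1, 1, 1)), "pad")
})

test_that("peak systole is the first-half argmax of mean LV speed", {
  f <- per_frame_speed_field(c(0.2, 0.8, 0.5, 0.3, 0.9, 0.1))
  mask <- array(TRUE, c(6, 6, 6))
  # frames 1..3 are the first half; the global max at frame 5 is excluded
  expect_identical(find_peak_systole(f, mask), 2L)

  const <- per_frame_speed_field(rep(0.5, 6))
  expect_identical(find_peak_systole(const, mask), 1L)     # tie -> earliest

  ph <- pulsatile_153()
  expect_identical(find_peak_systole(ph$field, ph$masks$lv), 6L)
  expect_identical(ph$truth$peak_systole_frame_true, 6L)
})

test_that("peak systole never falls in the second half of the cycle", {
  set.seed(11)
  for (T in c(5, 6, 24)) {
    sp <- stats::runif(T)
    f <- per_frame_speed_field(sp)
    mask <- array(TRUE, c(6, 6, 6))
    expect_lte(find_peak_systole(f, mask), ceiling(T / 2))
  }
  expect_error(find_peak_systole(per_frame_speed_field(c(1, 1)),
                                 array(FALSE, c(6, 6, 6))), "empty")
})
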