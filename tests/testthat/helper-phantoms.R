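# Shared fixtures: phantoms are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_config <- function(...) analysis_config(...)

# Clean steady parabolic tube: vmax 1 m/s, R 10 mm, no corruption.
clean_parabolic <- function() {
  cached("clean_parabolic", function() {
    make_tube_phantom(
      phantom_spec(radius = 10, profile_exponent = 2,
                   vmax_waveform = rep(1, 24), noise_frac = 0, seed = 1),
      test_config())
  })
}

# Pulsatile parabolic tube, vmax 1.53 m/s peaking at frame 6, clean.
pulsatile_153 <- function() {
  cached("pulsatile_153", function() {
    make_tube_phantom(
      phantom_spec(radius = 10, profile_exponent = 2,
                   vmax_waveform = 1.53 * systolic_waveform(24, 2:10),
                   noise_frac = 0, seed = 1),
      test_config())
  })
}

# A uniform velocity field: every voxel gets the vector v at every frame.
uniform_field <- function(v, dim = c(8, 8, 8), n_frames = 2,
                          spacing = c(2, 2, 2), frame_duration = 300,
                          venc = 2) {
  data <- array(0, c(dim, n_frames, 3))
  for (c in 1:3) data[, , , , c] <- v[c]
  velocity_field(data, spacing = spacing, frame_duration = frame_duration,
                 venc = venc)
}

# Field whose speed is spatially uniform but varies per frame (z-component).
per_frame_speed_field <- function(speeds, dim = c(6, 6, 6),
                                  spacing = c(2, 2, 2), venc = 5) {
  data <- array(0, c(dim, length(speeds), 3))
  for (t in seq_along(speeds)) data[, , , t, 3] <- speeds[t]
  velocity_field(data, spacing = spacing, frame_duration = 100, venc = venc)
}

# Axis-aligned digitised solid cylinder mask (axis along z), padded.
cylinder_mask <- function(radius = 10, length = 40, spacing = c(2.4, 2.4, 2.5),
                          pad = 3) {
  nxy <- 2 * ceiling((radius + pad * max(spacing)) / spacing[1]) + 3
  nz <- ceiling(length / spacing[3]) + 2 * pad
  cx <- (nxy - 1) / 2 * spacing[1]
  xs <- (seq_len(nxy) - 1) * spacing[1]
  r <- sqrt(outer((xs - cx)^2, (xs - cx)^2, "+"))
  disc <- r <= radius
  zs <- (seq_len(nz) - 1) * spacing[3]
  zc <- (nz - 1) / 2 * spacing[3]
  inz <- abs(zs - zc) <= length / 2
  mask <- array(FALSE, c(nxy, nxy, nz))
  for (k in which(inz)) mask[, , k] <- disc
  list(mask = mask, spacing = c(spacing[1], spacing[1], spacing[3]),
       in_z = inz, radius = radius, length = sum(inz) * spacing[3])
}
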