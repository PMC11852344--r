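# Synthetic pulsatile tube-flow phantoms with analytic ground truth.
#
# The flow model is quasi-steady power-law tube flow: at every frame the
# axial velocity is v(r, t) = vmax(t) (1 - (r/R)^n) inside a straight tube
# of radius R, zero outside. The profile shape (exponent n) is fixed over
# the cycle and only the centreline amplitude is modulated, which keeps
# every derived quantity in closed form:
#   wall shear stress   tau(t) = mu n vmax(t) / R
#   mean KE density     ke(t)  = 1/2 rho vmax(t)^2 g(n),
#                       g(n)   = 1 - 4/(n+2) + 1/(n+1)
#   flow rate           Q(t)   = pi R^2 vmax(t) n/(n+2)

#' Kinetic-energy shape factor of the power-law profile
#'
#' `g(n) = 1 - 4/(n+2) + 1/(n+1)`, the cross-section average of
#' `(1 - (r/R)^n)^2`. `g(2) = 1/3` (parabolic); `g -> 1` as `n -> Inf`
#' (plug flow).
#'
#' @param n Profile exponent, >= 1.
#' @return Dimensionless factor in (0, 1).
#' @export
ke_shape_factor <- function(n) 1 - 4 / (n + 2) + 1 / (n + 1)

#' Exact wall shear stress of the power-law profile
#'
#' The analytic oracle for the WSS metric: the wall shear of
#' `v(r) = vmax (1 - (r/R)^n)` is `mu n vmax / R`.
#'
#' @param vmax Centreline peak velocity in m/s.
#' @param radius Tube radius in m.
#' @param mu Dynamic viscosity in Pa s.
#' @param n Profile exponent.
#' @return Wall shear stress in Pa.
#' @export
poiseuille_wall_shear <- function(vmax, radius, mu, n) {
  if (any(c(vmax, radius, mu, n) <= 0)) {
    stop("domain error: all inputs must be > 0", call. = FALSE)
  }
  mu * n * vmax / radius
}

#' Exact cross-section-averaged kinetic energy density
#'
#' The analytic oracle for the KE metric: `1/2 rho vmax^2 g(n)` in J/m3,
#' numerically equal to the clinical "mJ/m3" convention (values are
#' consistent with mJ/L, i.e. J/m3).
#'
#' @param vmax Centreline peak velocity in m/s.
#' @param rho Density in kg/m3.
#' @param n Profile exponent.
#' @return Mean kinetic energy density in J/m3.
#' @export
powerlaw_mean_ke_density <- function(vmax, rho, n) {
  if (any(c(vmax, rho, n) <= 0)) {
    stop("domain error: all inputs must be > 0", call. = FALSE)
  }
  0.5 * rho * vmax^2 * ke_shape_factor(n)
}

#' Invert the closed forms: find (vmax, n) matching WSS and KE targets
#'
#' Solves `mu n vmax / R = target_wss` and
#' `1/2 rho vmax^2 g(n) = target_ke` for the centreline velocity and
#' profile exponent. Eliminating vmax gives `g(n)/n^2 = C` with
#' `C = 2 ke mu^2 / (rho tau^2 R^2)`; `g(n)/n^2` is strictly decreasing on
#' `[1, 20]`, so a deterministic bisection finds the unique root when one
#' exists.
#'
#' @param target_wss Target wall shear stress in Pa.
#' @param target_ke Target mean kinetic energy density in J/m3.
#' @param radius Tube radius in m.
#' @param config An [analysis_config()] supplying mu and rho.
#' @param tol Relative tolerance of the root.
#' @return List with `vmax` (m/s) and `n`.
#' @export
calibrate_segment <- function(target_wss, target_ke, radius,
                              config = analysis_config(), tol = 1e-9) {
  if (any(c(target_wss, target_ke, radius) <= 0)) {
    stop("domain error: targets and radius must be > 0", call. = FALSE)
  }
  C <- 2 * target_ke * config$mu^2 / (config$rho * target_wss^2 * radius^2)
  h <- function(n) ke_shape_factor(n) / n^2 - C
  lo <- 1; hi <- 20
  if (h(lo) < 0) {
    stop(sprintf(paste0("infeasible target: g(n)/n^2 = %.4g exceeds g(1) = 1/6 ",
                        "at n = 1; targets need a larger radius ",
                        "(minimum feasible radius %.4g m)"),
                 C, config$mu * sqrt(12 * target_ke / config$rho) / target_wss),
         call. = FALSE)
  }
  if (h(hi) > 0) {
    stop(sprintf("infeasible target: g(n)/n^2 = %.4g below g(20)/400; no root for n <= 20",
                 C), call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) < tol * mid) break
  }
  n <- (lo + hi) / 2
  vmax <- target_wss * radius / (config$mu * n)
  list(vmax = vmax, n = n)
}

#' Specification of one synthetic tube phantom
#'
#' Geometry, flow waveform and corruption model for one vessel segment.
#' Defaults mirror the emulated acquisition: 2.4 x 2.4 mm in-plane
#' resolution, 2.5 mm slices, 24 cardiac frames over a 1000 ms cycle.
#' The tube axis is oblique to the grid by default (about 10 degrees) so
#' that successive slices sample different sub-voxel grid alignments, as
#' real vessels do relative to scanner axes.
#'
#' @param radius Tube radius in mm.
#' @param length Axial length of the analysis segment in mm.
#' @param profile_exponent Power-law exponent n >= 1.
#' @param vmax_waveform Per-frame centreline peak velocity in m/s
#'   (length `n_frames`); see [systolic_waveform()].
#' @param spacing Voxel size in mm.
#' @param n_frames Number of cardiac frames.
#' @param rr_interval Cardiac cycle length in ms.
#' @param venc Velocity-encoding limit in m/s.
#' @param noise_frac Gaussian velocity-noise SD as a fraction of venc,
#'   independent per component (the standard phase-contrast noise model).
#' @param offset_coeffs 3 x 10 matrix of background phase-offset polynomial
#'   coefficients (m/s) per velocity component over the monomials
#'   1, x, y, z, x2, y2, z2, xy, xz, yz in grid coordinates normalised to
#'   \[-1, 1\]; NULL for no offset.
#' @param alias Wrap velocities beyond +/- venc into (-venc, venc]?
#' @param systole_frames Frame indices (1-based) of systole.
#' @param axis Tube axis direction (need not be unit length).
#' @param center_offset In-plane (x, y) offset of the tube axis from the
#'   grid centre, mm.
#' @param margin Clear margin around the lumen in mm (static tissue lives
#'   there).
#' @param segment Which analysis mask the lumen fills: "lvot" or "aorta".
#' @param seed Integer seed for the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(radius,
                         length = 50,
                         profile_exponent = 2,
                         vmax_waveform = NULL,
                         spacing = c(2.4, 2.4, 2.5),
                         n_frames = 24L,
                         rr_interval = 1000,
                         venc = 2.0,
                         noise_frac = 0,
                         offset_coeffs = NULL,
                         alias = FALSE,
                         systole_frames = 2:10,
                         axis = c(0.15, 0.09, 1),
                         center_offset = c(0, 0),
                         margin = 8,
                         segment = c("aorta", "lvot"),
                         seed = 1L) {
  segment <- match.arg(segment)
  if (is.null(vmax_waveform)) {
    vmax_waveform <- systolic_waveform(n_frames, systole_frames)
  }
  if (length(vmax_waveform) != n_frames) {
    stop("vmax_waveform must have one entry per cardiac frame", call. = FALSE)
  }
  if (profile_exponent < 1) stop("profile exponent must be >= 1", call. = FALSE)
  if (noise_frac < 0) stop("noise_frac must be >= 0", call. = FALSE)
  if (radius < 3 * max(spacing)) {
    stop(sprintf(paste0("resolution error: radius %.2f mm under-resolved; ",
                        "need >= 3 voxels across the radius (>= %.2f mm)"),
                 radius, 3 * max(spacing)), call. = FALSE)
  }
  structure(list(radius = radius, length = length,
                 profile_exponent = profile_exponent,
                 vmax_waveform = vmax_waveform, spacing = spacing,
                 n_frames = as.integer(n_frames), rr_interval = rr_interval,
                 venc = venc, noise_frac = noise_frac,
                 offset_coeffs = offset_coeffs, alias = alias,
                 systole_frames = as.integer(systole_frames),
                 axis = axis / sqrt(sum(axis^2)),
                 center_offset = center_offset, margin = margin,
                 segment = segment, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Systolic flow waveform
#'
#' Per-frame centreline velocity shape: a raised-sine systolic lobe
#' `sin(pi (t - t0)/(t1 - t0))^(2 alpha)` over `systole_frames` (peak 1 at
#' the window centre, 0 elsewhere), optionally followed by a flattened-sine
#' diastolic forward lobe of relative amplitude `beta` over
#' `diastole_frames`. Multiply by the centreline peak velocity to get
#' `vmax_waveform` in m/s.
#'
#' @param n_frames Number of cardiac frames.
#' @param systole_frames Systolic window (1-based, inside the first half).
#' @param alpha Systolic lobe shape exponent; larger is sharper.
#' @param beta Diastolic lobe relative amplitude (0 for none).
#' @param diastole_frames Diastolic window (1-based).
#' @return Numeric vector of length `n_frames` with maximum 1 at the
#'   systolic peak.
#' @export
systolic_waveform <- function(n_frames = 24L, systole_frames = 2:10,
                              alpha = 1, beta = 0, diastole_frames = 13:23) {
  w <- numeric(n_frames)
  t0 <- min(systole_frames); t1 <- max(systole_frames)
  w[systole_frames] <- sin(pi * (systole_frames - t0) / (t1 - t0))^(2 * alpha)
  if (beta > 0) {
    d0 <- min(diastole_frames); d1 <- max(diastole_frames)
    w[diastole_frames] <- w[diastole_frames] +
      beta * sin(pi * (diastole_frames - d0) / (d1 - d0))^0.4
  }
  w
}

# Geometry of an oblique tube on the voxel grid: per-voxel axial coordinate
# s and radial distance r from the axis (both mm).
tube_geometry <- function(spec) {
  u <- spec$axis
  sp <- spec$spacing
  zlen <- spec$length / u[3] + 2 * sp[3]          # grid long enough for the segment
  nz <- ceiling(zlen / sp[3]) + 1L
  drift <- (nz - 1) * sp[3] * abs(u[1:2]) / u[3]
  nx <- ceiling((2 * (spec$radius + spec$margin) + drift[1]) / sp[1]) + 1L
  ny <- ceiling((2 * (spec$radius + spec$margin) + drift[2]) / sp[2]) + 1L
  ctr <- c((nx - 1) / 2 * sp[1] + spec$center_offset[1],
           (ny - 1) / 2 * sp[2] + spec$center_offset[2],
           (nz - 1) / 2 * sp[3])
  xs <- (seq_len(nx) - 1) * sp[1]
  ys <- (seq_len(ny) - 1) * sp[2]
  zs <- (seq_len(nz) - 1) * sp[3]
  px <- array(rep(xs, ny * nz), c(nx, ny, nz)) - ctr[1]
  py <- array(rep(rep(ys, each = nx), nz), c(nx, ny, nz)) - ctr[2]
  pz <- array(rep(zs, each = nx * ny), c(nx, ny, nz)) - ctr[3]
  s <- px * u[1] + py * u[2] + pz * u[3]
  r <- sqrt(pmax((px - s * u[1])^2 + (py - s * u[2])^2 + (pz - s * u[3])^2, 0))
  list(dim = c(nx, ny, nz), ctr = ctr, s = s, r = r, u = u)
}

#' Generate a synthetic 4D-flow tube phantom with analytic ground truth
#'
#' Builds the velocity field (power-law profile at voxel centres, exactly),
#' a magnitude series (bright lumen on dim tissue), segmentation masks and
#' the analytic truth record. Corruptions are applied in the order noise,
#' then polynomial background offset, then venc wrap-around; the truth is
#' computed from the closed forms before any corruption and is therefore
#' independent of the noise seed. Output is reproducible for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param config An [analysis_config()] (supplies mu and rho for the truth).
#' @return A list of class `tube_phantom` with elements `field`
#'   ([velocity_field()]), `magnitude`, `masks` ([mask_set()]; the full
#'   lumen in `lumen`, the z-trimmed analysis segment in the slot named by
#'   `spec$segment` and in `lv`, static tissue in `static_tissue`), `truth`
#'   and `spec`.
#' @export
make_tube_phantom <- function(spec, config = analysis_config()) {
  geo <- tube_geometry(spec)
  d <- geo$dim
  R <- spec$radius
  n <- spec$profile_exponent
  lumen <- geo$r <= R
  profile <- ifelse(lumen, 1 - (geo$r / R)^n, 0)
  smax <- spec$length / 2
  seg <- lumen & abs(geo$s) <= smax
  static <- geo$r >= R + 2 * max(spec$spacing)

  T <- spec$n_frames
  data <- array(0, c(d, T, 3))
  for (t in seq_len(T)) {
    amp <- spec$vmax_waveform[t]
    for (c in 1:3) data[, , , t, c] <- profile * (amp * geo$u[c])
  }

  # truth from the closed forms, before corruption
  vpk <- spec$vmax_waveform
  dt_s <- spec$rr_interval / T / 1000
  truth <- list(
    wss_true = config$mu * n * vpk / (R / 1000),
    ke_density_true = 0.5 * config$rho * vpk^2 * ke_shape_factor(n),
    peak_velocity_true = max(vpk[seq_len(ceiling(T / 2))]),
    stroke_volume_true = sum(pi * R^2 * vpk * n / (n + 2)) * dt_s,
    peak_systole_frame_true = which.max(vpk[seq_len(ceiling(T / 2))])
  )
  truth$wss_peak_true <- truth$wss_true[truth$peak_systole_frame_true]
  truth$ke_peak_true <- truth$ke_density_true[truth$peak_systole_frame_true]

  # corruption: noise -> offset -> wrap
  set.seed(spec$seed)
  if (spec$noise_frac > 0) {
    data <- data + array(stats::rnorm(length(data),
                                      sd = spec$noise_frac * spec$venc),
                         dim(data))
  }
  if (!is.null(spec$offset_coeffs)) {
    X <- poly_design(d, order = 2)
    for (c in 1:3) {
      off <- array(X %*% spec$offset_coeffs[c, ], d)
      for (t in seq_len(T)) data[, , , t, c] <- data[, , , t, c] + off
    }
  }
  if (spec$alias) {
    v <- spec$venc
    data <- ((data + v) %% (2 * v)) - v
  }

  field <- velocity_field(data, spacing = spec$spacing,
                          frame_duration = spec$rr_interval / T,
                          venc = spec$venc, rr_interval = spec$rr_interval)
  mag <- array(rep(ifelse(lumen, 100, 20), T), c(d, T))
  masks_args <- list(lv = seg, static_tissue = static, lumen = lumen)
  masks_args[[spec$segment]] <- seg
  structure(list(field = field,
                 magnitude = magnitude_series(mag),
                 masks = do.call(mask_set, masks_args),
                 truth = truth, spec = spec),
            class = "tube_phantom")
}

# Second-order polynomial design matrix over a grid, coordinates normalised
# to [-1, 1] per axis. Column order: 1, x, y, z, x2, y2, z2, xy, xz, yz.
poly_design <- function(d, order = 2, subset = NULL) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  sc <- function(n) if (n > 1) seq(-1, 1, length.out = n) else 0
  x <- array(rep(sc(nx), ny * nz), d)
  y <- array(rep(rep(sc(ny), each = nx), nz), d)
  z <- array(rep(sc(nz), each = nx * ny), d)
  if (!is.null(subset)) {
    x <- x[subset]; y <- y[subset]; z <- z[subset]
  }
  X <- cbind(1, as.vector(x), as.vector(y), as.vector(z))
  if (order >= 2) {
    X <- cbind(X, as.vector(x)^2, as.vector(y)^2, as.vector(z)^2,
               as.vector(x * y), as.vector(x * z), as.vector(y * z))
  }
  X
}
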