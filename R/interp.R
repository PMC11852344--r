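# Grid interpolation and smoothing primitives shared by surface extraction,
# wall shear stress sampling and valve-plane resampling.
#
# Conventions: voxel (i, j, k) (1-based) has its centre at physical
# ((i-1) dx, (j-1) dy, (k-1) dz) mm. "Voxel coordinates" are 0-based
# physical/spacing, so voxel centres sit at integer coordinates.

#' Trilinear interpolation of a 3-D volume at arbitrary points
#'
#' @param vol 3-D numeric array.
#' @param pts N x 3 matrix of 0-based voxel coordinates.
#' @return List with `value` (length N; 0 where out of bounds) and
#'   `inside` (logical, FALSE where any contributing corner with non-zero
#'   weight falls outside the volume).
#' @keywords internal
interp_trilinear <- function(vol, pts) {
  d <- dim(vol)
  p0 <- floor(pts)
  f <- pts - p0
  val <- numeric(nrow(pts))
  inside <- rep(TRUE, nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- p0[, 1] + dx
    iy <- p0[, 2] + dy
    iz <- p0[, 3] + dz
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
         (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
         (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    inb <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
    inside <- inside & (inb | w < 1e-12)
    ix <- pmin(pmax(ix, 0), d[1] - 1)
    iy <- pmin(pmax(iy, 0), d[2] - 1)
    iz <- pmin(pmax(iz, 0), d[3] - 1)
    val <- val + w * vol[cbind(ix + 1L, iy + 1L, iz + 1L)]
  }
  list(value = val, inside = inside)
}

#' Separable Gaussian smoothing, isotropic in mm
#'
#' @param a 3-D numeric array.
#' @param sigma_mm Gaussian sigma in mm.
#' @param spacing Voxel size in mm, length 3.
#' @return Smoothed array (replicate-padded at borders).
#' @keywords internal
gaussian_smooth3 <- function(a, sigma_mm, spacing) {
  for (ax in 1:3) {
    sg <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * sg))
    k <- stats::dnorm(seq(-r, r), sd = sg)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(a, perm)
    dm <- dim(m)
    m2 <- matrix(m, nrow = dm[1])
    n <- dm[1]
    out <- matrix(0, n, ncol(m2))
    for (j in seq_along(k)) {
      idx <- pmin(pmax(seq_len(n) + j - r - 1L, 1L), n)
      out <- out + k[j] * m2[idx, , drop = FALSE]
    }
    dim(out) <- dm
    a <- aperm(out, order(perm))
  }
  a
}

#' Central-difference gradient of a 3-D volume, per mm
#' @keywords internal
gradient3 <- function(a, spacing) {
  d <- dim(a)
  g <- array(0, c(d, 3))
  g[2:(d[1] - 1), , , 1] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) / (2 * spacing[1])
  g[, 2:(d[2] - 1), , 2] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) / (2 * spacing[2])
  g[, , 2:(d[3] - 1), 3] <- (a[, , 3:d[3]] - a[, , 1:(d[3] - 2)]) / (2 * spacing[3])
  g
}

#' Sample the three velocity components of one frame at physical points
#'
#' @param field A [velocity_field()].
#' @param frame Frame index (1-based).
#' @param pts N x 3 matrix of physical coordinates in mm.
#' @return List with `v` (N x 3 matrix, m/s) and `inside` (logical N).
#' @keywords internal
sample_velocity <- function(field, frame, pts) {
  pv <- sweep(pts, 2, field$spacing, "/")
  v <- matrix(0, nrow(pts), 3)
  inside <- rep(TRUE, nrow(pts))
  for (c in 1:3) {
    r <- interp_trilinear(field$data[, , , frame, c], pv)
    v[, c] <- r$value
    inside <- inside & r$inside
  }
  list(v = v, inside = inside)
}
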