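# Preprocessing of phase-contrast velocity fields: anti-aliasing,
# background phase-offset correction and PC-MRA construction.

#' Detect static tissue from temporal velocity statistics
#'
#' A voxel is static when both the temporal SD and the temporal mean of its
#' speed stay below `static_sd_frac * venc`. Static voxels anchor the
#' background phase-offset fit.
#'
#' @param field A [velocity_field()] with at least 4 frames.
#' @param config An [analysis_config()].
#' @return Logical 3-D mask. Warns when fewer than 100 voxels qualify.
#' @export
detect_static_tissue <- function(field, config = analysis_config()) {
  if (field$n_frames < 4) {
    stop("need at least 4 frames to detect static tissue", call. = FALSE)
  }
  sp <- speed_array(field)
  d <- dim(sp)
  m <- matrix(sp, ncol = d[4])
  mu_t <- rowMeans(m)
  sd_t <- sqrt(pmax(rowMeans(m^2) - mu_t^2, 0) * d[4] / (d[4] - 1))
  thr <- config$static_sd_frac * field$venc
  mask <- array(sd_t < thr & mu_t < thr, d[1:3])
  if (sum(mask) < 100) {
    warning(sprintf("only %d static voxels detected (threshold %.3f m/s)",
                    sum(mask), thr), call. = FALSE)
  }
  mask
}

#' Correct background phase offsets against static tissue
#'
#' Fits, per frame and velocity component, a second-order spatial
#' polynomial to the velocities of static voxels by least squares,
#' averages the coefficients over frames (phase-contrast offsets are
#' temporally stable) and subtracts the fitted polynomial from the whole
#' volume. Falls back to a constant (order 0) fit with a warning when the
#' static voxels leave the design rank-deficient.
#'
#' @param field A [velocity_field()].
#' @param static_mask Logical 3-D mask of static voxels (non-empty).
#' @param config An [analysis_config()].
#' @return The corrected [velocity_field()].
#' @export
correct_background_offset <- function(field, static_mask,
                                      config = analysis_config()) {
  check_mask_grid(static_mask, field)
  ns <- sum(static_mask)
  if (ns == 0) stop("static mask is empty", call. = FALSE)
  d <- grid_dim(field)
  Xs <- poly_design(d, order = 2, subset = static_mask)
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    warning("static voxels leave the 2nd-order fit rank-deficient; ",
            "falling back to constant offset", call. = FALSE)
    Xs <- Xs[, 1, drop = FALSE]
    qrX <- qr(Xs)
  }
  Xall <- poly_design(d, order = 2)[, seq_len(ncol(Xs)), drop = FALSE]
  out <- field
  for (c in 1:3) {
    comp <- field$data[, , , , c]
    y <- matrix(comp[rep_len(as.vector(static_mask), length(comp))],
                nrow = ns)
    beta <- rowMeans(qr.coef(qrX, y))            # frame-averaged coefficients
    off <- as.vector(Xall %*% beta)
    out$data[, , , , c] <- comp - off
  }
  out
}

#' Temporal velocity anti-aliasing
#'
#' Scans each voxel/component time series in frame order; whenever the
#' frame-to-frame difference exceeds venc in magnitude, the later value is
#' shifted by the multiple of 2 venc that minimises the jump (a tie at
#' exactly venc is left alone). The correction accumulates along the
#' series, so output values may exceed venc. Idempotent on series whose
#' jumps are all within venc.
#'
#' @param field A [velocity_field()].
#' @return The unwrapped [velocity_field()], with attribute `n_unwrapped`
#'   (count of modified voxel-frames).
#' @export
unalias_velocity <- function(field) {
  v <- field$venc
  d <- dim(field$data)
  m <- matrix(field$data, ncol = d[4] * d[5])
  dim(m) <- c(prod(d[1:3]), d[4], d[5])
  n_fix <- 0L
  for (c in 1:3) {
    for (t in 2:d[4]) {
      jump <- m[, t, c] - m[, t - 1, c]
      k <- round(jump / (2 * v))
      k[abs(jump) <= v] <- 0
      hit <- k != 0
      if (any(hit)) {
        m[hit, t, c] <- m[hit, t, c] - 2 * v * k[hit]
        n_fix <- n_fix + sum(hit)
      }
    }
  }
  out <- field
  out$data <- array(m, d)
  attr(out, "n_unwrapped") <- n_fix
  out
}

#' 3-D phase-contrast angiogram
#'
#' `pcmra(x) = mean over frames of magnitude(x, t) * |v(x, t)|`: the
#' magnitude images multiplied with absolute velocity and averaged over
#' time, which lights up moving blood against static tissue.
#'
#' @param mag A [magnitude_series()].
#' @param field The paired [velocity_field()].
#' @return Object of class `pcmra`: list with `data` (non-negative 3-D
#'   array) and `spacing` (mm).
#' @export
compute_pcmra <- function(mag, field) {
  if (!identical(dim(mag$data), dim(field$data)[1:4])) {
    stop("magnitude and velocity grids do not match", call. = FALSE)
  }
  sp <- speed_array(field)
  d <- dim(sp)
  pc <- array(rowMeans(matrix(mag$data * sp, ncol = d[4])), d[1:3])
  structure(list(data = pc, spacing = field$spacing), class = "pcmra")
}

#' Full preprocessing: anti-aliasing then background offset correction
#'
#' Inverts the corruption chain of the acquisition model: wrap-around is
#' undone first (it happened last), then the temporally stable background
#' offset is estimated from static tissue and removed.
#'
#' @param field A [velocity_field()].
#' @param config An [analysis_config()].
#' @param static_mask Optional static-tissue mask; detected from the data
#'   when NULL.
#' @param unalias Run anti-aliasing?
#' @param offset Run offset correction?
#' @return List with `field` (corrected), `static_mask` and `n_unwrapped`.
#' @export
preprocess_field <- function(field, config = analysis_config(),
                             static_mask = NULL, unalias = TRUE,
                             offset = TRUE) {
  n_unwrapped <- 0L
  if (unalias) {
    field <- unalias_velocity(field)
    n_unwrapped <- attr(field, "n_unwrapped")
  }
  if (offset) {
    if (is.null(static_mask)) static_mask <- detect_static_tissue(field, config)
    field <- correct_background_offset(field, static_mask, config)
  }
  list(field = field, static_mask = static_mask, n_unwrapped = n_unwrapped)
}
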