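#' Time-resolved three-directional velocity field
#'
#' The central container of the pipeline: a 4-D grid of 3-component blood
#' velocity vectors (m/s), one volume per cardiac frame, with acquisition
#' geometry and timing. Velocities are stored in m/s, voxel spacing in mm
#' and time in ms throughout; unit conversions happen exactly once, inside
#' each metric computation.
#'
#' @param data Numeric array of dim `c(nx, ny, nz, n_frames, 3)` in m/s.
#' @param spacing Voxel size in mm, length 3, all > 0.
#' @param frame_duration Duration of one cardiac frame in ms.
#' @param venc Velocity-encoding limit in m/s; velocities beyond +/- venc
#'   alias by multiples of 2 venc.
#' @param rr_interval Cardiac cycle length in ms. Defaults to
#'   `frame_duration * n_frames`.
#'
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(data, spacing, frame_duration, venc,
                           rr_interval = NULL) {
  if (length(dim(data)) != 5 || dim(data)[5] != 3) {
    stop("velocity data must be a 5-D array (x, y, z, t, component)",
         call. = FALSE)
  }
  n_frames <- dim(data)[4]
  if (is.null(rr_interval)) rr_interval <- frame_duration * n_frames
  f <- structure(
    list(data = data,
         spacing = as.numeric(spacing),
         frame_duration = as.numeric(frame_duration),
         n_frames = as.integer(n_frames),
         venc = as.numeric(venc),
         rr_interval = as.numeric(rr_interval)),
    class = "velocity_field")
  validate_velocity_field(f)
}

validate_velocity_field <- function(f) {
  if (f$n_frames < 2) stop("need at least 2 cardiac frames", call. = FALSE)
  if (length(f$spacing) != 3 || any(f$spacing <= 0)) {
    stop("spacing must be 3 positive voxel sizes (mm)", call. = FALSE)
  }
  if (!is.finite(f$venc) || f$venc <= 0) stop("venc must be > 0", call. = FALSE)
  if (abs(f$frame_duration * f$n_frames - f$rr_interval) > f$frame_duration) {
    stop("frame_duration * n_frames must match rr_interval within one frame",
         call. = FALSE)
  }
  if (anyNA(f$data) || any(!is.finite(f$data))) {
    stop("velocity data contains non-finite values", call. = FALSE)
  }
  f
}

grid_dim <- function(field) dim(field$data)[1:3]

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<velocity_field> %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], x$n_frames))
  cat(sprintf("  spacing %s mm | frame %.2f ms | RR %.0f ms | venc %.2f m/s\n",
              paste(format(x$spacing), collapse = " x "),
              x$frame_duration, x$rr_interval, x$venc))
  cat(sprintf("  speed range %.3f .. %.3f m/s\n",
              0, max(sqrt(rowSums(matrix(x$data, ncol = 3)^2)))))
  invisible(x)
}

#' Phase-contrast magnitude image series
#'
#' Non-negative scalar signal on the same grid and frames as a paired
#' [velocity_field()].
#'
#' @param data Numeric array of dim `c(nx, ny, nz, n_frames)`, values >= 0.
#' @return An object of class `magnitude_series`.
#' @export
magnitude_series <- function(data) {
  if (length(dim(data)) != 4) {
    stop("magnitude data must be a 4-D array (x, y, z, t)", call. = FALSE)
  }
  if (anyNA(data) || any(data < 0)) {
    stop("magnitude values must be finite and >= 0", call. = FALSE)
  }
  structure(list(data = data), class = "magnitude_series")
}

#' Labelled segmentation masks on the velocity grid
#'
#' Binary 3-D masks for the left ventricle, LVOT, ascending aorta and
#' static tissue. An optional `lumen` mask (the full flow channel) marks
#' where blood moves; surface extraction uses it to tell vessel wall from
#' open flow cross-sections. Masks may be empty as long as the metrics that
#' need them are not requested.
#'
#' @param lv,lvot,aorta,static_tissue Logical 3-D arrays on the velocity grid.
#' @param lumen Optional logical 3-D array, the full flow region.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(lv = NULL, lvot = NULL, aorta = NULL,
                     static_tissue = NULL, lumen = NULL) {
  m <- list(lv = lv, lvot = lvot, aorta = aorta,
            static_tissue = static_tissue, lumen = lumen)
  dims <- lapply(Filter(Negate(is.null), m), dim)
  if (length(dims) > 0 &&
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all masks must share the same grid shape", call. = FALSE)
  }
  if (!is.null(m$lv) && !is.null(m$static_tissue) &&
      any(m$lv & m$static_tissue)) {
    stop("lv and static_tissue masks must be disjoint", call. = FALSE)
  }
  structure(m, class = "mask_set")
}

check_mask_grid <- function(mask, field) {
  if (!identical(dim(mask), grid_dim(field))) {
    stop("mask grid does not match the velocity grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-frame speed array
#'
#' @param field A [velocity_field()].
#' @return Array `c(nx, ny, nz, n_frames)` of voxel speeds (m/s).
#' @keywords internal
speed_array <- function(field) {
  d <- dim(field$data)
  sqrt(field$data[, , , , 1]^2 + field$data[, , , , 2]^2 +
         field$data[, , , , 3]^2)
}
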