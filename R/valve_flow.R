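# Transvalvular flow through a time-resolved valve plane.

#' Time-resolved valve plane track
#'
#' One plane per cardiac frame: origin (mm), unit normal, and aperture
#' radius (mm). A single origin/normal/radius is recycled over all frames
#' (a static plane).
#'
#' @param n_frames Number of cardiac frames.
#' @param origin N x 3 matrix (or length-3 vector) of plane origins, mm.
#' @param normal N x 3 matrix (or length-3 vector) of plane normals
#'   (normalised internally).
#' @param radius Aperture radius per frame (recycled), mm, > 0.
#' @return Object of class `valve_plane_track`.
#' @export
valve_plane_track <- function(n_frames, origin, normal, radius) {
  origin <- matrix(origin, nrow = n_frames, ncol = 3, byrow = is.null(dim(origin)))
  normal <- matrix(normal, nrow = n_frames, ncol = 3, byrow = is.null(dim(normal)))
  radius <- rep_len(radius, n_frames)
  if (any(radius <= 0)) stop("aperture radius must be > 0", call. = FALSE)
  nn <- sqrt(rowSums(normal^2))
  if (any(nn < 1e-12)) stop("zero-length plane normal", call. = FALSE)
  structure(list(origin = origin, normal = normal / nn, radius = radius,
                 n_frames = as.integer(n_frames)),
            class = "valve_plane_track")
}

#' Read/write a valve plane track as CSV
#'
#' Columns: frame, ox, oy, oz, nx, ny, nz, radius_mm.
#'
#' @param path CSV path.
#' @param track A [valve_plane_track()] (for writing).
#' @return A [valve_plane_track()] / `path` invisibly.
#' @export
read_valve_track <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "ox", "oy", "oz", "nx", "ny", "nz", "radius_mm")
  if (!all(need %in% names(df))) {
    stop("track CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$frame), ]
  valve_plane_track(nrow(df),
                    origin = as.matrix(df[, c("ox", "oy", "oz")]),
                    normal = as.matrix(df[, c("nx", "ny", "nz")]),
                    radius = df$radius_mm)
}

#' @rdname read_valve_track
#' @export
write_valve_track <- function(track, path) {
  df <- data.frame(frame = seq_len(track$n_frames),
                   ox = track$origin[, 1], oy = track$origin[, 2],
                   oz = track$origin[, 3],
                   nx = track$normal[, 1], ny = track$normal[, 2],
                   nz = track$normal[, 3],
                   radius_mm = track$radius)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Forward and backward transvalvular flow
#'
#' Per frame, the through-plane velocity component `v . n` is resampled by
#' trilinear interpolation on a uniform 2-D grid covering the aperture disc
#' (grid spacing at most half the smallest voxel dimension; each sample
#' carries an equal share of the true disc area, so uniform plug flow is
#' reproduced exactly). The flow rate is `Q(t) = sum (v . n) dA` (ml/s);
#' forward volume per beat integrates the positive part of Q over the
#' cycle, backward the negative part, both in ml.
#'
#' @param field A [velocity_field()].
#' @param track A [valve_plane_track()] with one plane per frame.
#' @param h Resampling grid spacing in mm; defaults to half the smallest
#'   voxel dimension.
#' @return Object of class `flow_result`: `q_ml_s` (per-frame flow rate),
#'   `forward`, `backward` (ml/beat).
#' @export
transvalvular_flow <- function(field, track, h = min(field$spacing) / 2) {
  if (track$n_frames != field$n_frames) {
    stop("track must have one plane per cardiac frame", call. = FALSE)
  }
  dt_s <- field$frame_duration / 1000
  extent <- (grid_dim(field) - 1) * field$spacing
  q <- numeric(field$n_frames)
  bad_frames <- integer(0)
  for (t in seq_len(field$n_frames)) {
    n <- track$normal[t, ]
    r <- track$radius[t]
    # orthonormal in-plane basis
    ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * n) * n
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2],
            n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    ab <- as.matrix(expand.grid(a = seq(-r, r, by = h), b = seq(-r, r, by = h)))
    ab <- ab[ab[, 1]^2 + ab[, 2]^2 <= r^2, , drop = FALSE]
    pts <- cbind(track$origin[t, 1] + ab[, 1] * e1[1] + ab[, 2] * e2[1],
                 track$origin[t, 2] + ab[, 1] * e1[2] + ab[, 2] * e2[2],
                 track$origin[t, 3] + ab[, 1] * e1[3] + ab[, 2] * e2[3])
    if (any(pts < -1e-9) || any(sweep(pts, 2, extent + 1e-9, ">"))) {
      bad_frames <- c(bad_frames, t)
      next
    }
    s <- sample_velocity(field, t, pts)
    vn <- s$v %*% n
    # mm2 x m/s = 1e-6 m3/s = 1 ml/s, so dA in mm2 gives Q in ml/s directly
    q[t] <- mean(vn) * pi * r^2
  }
  if (length(bad_frames) > 0) {
    stop("out-of-bounds error: valve aperture leaves the volume at frame(s) ",
         paste(bad_frames, collapse = ", "), call. = FALSE)
  }
  structure(list(q_ml_s = q,
                 forward = sum(pmax(q, 0)) * dt_s,
                 backward = sum(-pmin(q, 0)) * dt_s),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("<flow_result> forward %.1f ml, backward %.1f ml per beat\n",
              x$forward, x$backward))
  invisible(x)
}
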