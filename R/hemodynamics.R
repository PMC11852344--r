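# Haemodynamic metrics at the peak-systolic frame: wall shear stress,
# peak velocity, kinetic energy density, simplified-Bernoulli gradients and
# contour-length strain.

#' Wall shear stress over a wall surface
#'
#' Per surface point: velocity is sampled by trilinear interpolation at the
#' configured distances along the inward normal, projected onto the local
#' tangent plane (normal component removed), and a quadratic through the
#' origin (no slip: v = 0 at the wall) is fitted per tangential component
#' by least squares over distance 0 and the sample distances. The WSS
#' vector is mu times the fitted wall gradient; the summary is the
#' area-weighted mean magnitude. Points whose samples leave the volume are
#' skipped and counted; more than 20% skipped raises a coverage error.
#'
#' @param field A [velocity_field()].
#' @param frame Frame index (1-based), usually from [find_peak_systole()].
#' @param surface A [extract_wall_surface()] result.
#' @param config An [analysis_config()]; uses `mu` and
#'   `wss_sample_distances` (mm).
#' @return Object of class `wss_field`: `vectors` (N x 3, Pa), `magnitude`
#'   (N, Pa), `summary` (area-weighted mean magnitude, Pa), `n_skipped`.
#' @export
compute_wss <- function(field, frame, surface, config = analysis_config()) {
  dists <- sort(config$wss_sample_distances)
  npt <- nrow(surface$points)
  k <- length(dists)
  vs <- array(0, c(npt, k, 3))
  inside <- rep(TRUE, npt)
  for (j in seq_len(k)) {
    p <- surface$points + dists[j] * surface$inward_normals
    s <- sample_velocity(field, frame, p)
    vs[, j, ] <- s$v
    inside <- inside & s$inside
  }
  n_skipped <- sum(!inside)
  if (n_skipped > 0.2 * npt) {
    stop(sprintf("surface-coverage error: %d of %d sample points outside the volume",
                 n_skipped, npt), call. = FALSE)
  }
  # tangential projection
  for (j in seq_len(k)) {
    vn <- rowSums(vs[, j, ] * surface$inward_normals)
    vs[, j, ] <- vs[, j, ] - vn * surface$inward_normals
  }
  # least-squares fit of v(d) = a d + b d^2 through the origin; the wall
  # gradient is a (per tangential component), in 1/s with d in metres
  dm <- dists / 1000
  X <- cbind(dm, dm^2)
  H <- solve(crossprod(X), t(X))[1, ]          # row extracting the slope
  tau <- matrix(0, npt, 3)
  for (c in 1:3) tau[, c] <- config$mu * as.vector(vs[, , c] %*% H)
  tau[!inside, ] <- NA
  mag <- sqrt(rowSums(tau^2))
  w <- surface$area_weights
  ok <- inside
  structure(list(vectors = tau, magnitude = mag,
                 summary = sum(w[ok] * mag[ok]) / sum(w[ok]),
                 n_skipped = n_skipped),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field> %d points, area-weighted mean %.3f Pa (%d skipped)\n",
              length(x$magnitude), x$summary, x$n_skipped))
  invisible(x)
}

#' Peak velocity within a mask
#'
#' Maximum voxel speed inside the mask at the given frame. Deliberately the
#' single maximum voxel (no percentile robustification): noise sensitivity
#' is accepted because the quantity is a peak.
#'
#' @param field A [velocity_field()].
#' @param frame Frame index (1-based).
#' @param mask Logical 3-D mask, non-empty.
#' @return Peak speed in m/s.
#' @export
peak_velocity <- function(field, frame, mask) {
  check_mask_grid(mask, field)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- field$data[, , , frame, ]
  max(sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)[mask])
}

#' Mean kinetic energy density within a mask
#'
#' Mean over mask voxels of `1/2 rho |v|^2` at the given frame, in J/m3 —
#' numerically the clinical "mJ/m3" convention (consistent with mJ/L).
#'
#' @param field A [velocity_field()].
#' @param frame Frame index (1-based).
#' @param mask Logical 3-D mask, non-empty.
#' @param config An [analysis_config()]; uses `rho`.
#' @return Mean kinetic energy density (J/m3).
#' @export
kinetic_energy_density <- function(field, frame, mask,
                                   config = analysis_config()) {
  check_mask_grid(mask, field)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- field$data[, , , frame, ]
  sq <- (v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)[mask]
  0.5 * config$rho * mean(sq)
}

#' Simplified-Bernoulli pressure gradients
#'
#' `dp = 4 v^2` (mmHg for v in m/s, the standard clinical simplification).
#' The maximum gradient uses the highest systolic peak velocity; the mean
#' gradient is the systolic time-average of the instantaneous `4 v^2`.
#'
#' @param vpeak_per_frame Per-frame peak velocity series (m/s).
#' @param systole_frames Frame indices (1-based) of systole.
#' @return List with `dp_mean` and `dp_max` in mmHg.
#' @export
bernoulli_gradient <- function(vpeak_per_frame, systole_frames) {
  if (length(vpeak_per_frame) == 0) stop("empty velocity series", call. = FALSE)
  if (length(systole_frames) == 0 ||
      any(systole_frames < 1 | systole_frames > length(vpeak_per_frame))) {
    stop("systole_frames must be non-empty indices into the series",
         call. = FALSE)
  }
  v <- vpeak_per_frame[systole_frames]
  list(dp_mean = mean(4 * v^2), dp_max = 4 * max(v)^2)
}

#' Longitudinal strain from contour lengths
#'
#' `(min_t L(t) - L(1)) / L(1) * 100`, with frame 1 the end-diastolic
#' reference; shortening is negative, and a series that only lengthens
#' yields 0.
#'
#' @param contour_lengths Per-frame contour length series (mm), all > 0.
#' @return Strain in percent (<= 0).
#' @export
longitudinal_strain <- function(contour_lengths) {
  if (length(contour_lengths) == 0) stop("empty length series", call. = FALSE)
  if (any(!is.finite(contour_lengths) | contour_lengths <= 0)) {
    stop("contour lengths must be positive", call. = FALSE)
  }
  (min(contour_lengths) - contour_lengths[1]) / contour_lengths[1] * 100
}

#' Per-frame peak speed within a mask
#' @keywords internal
peak_velocity_series <- function(field, mask) {
  vapply(seq_len(field$n_frames),
         function(t) peak_velocity(field, t, mask), numeric(1))
}

#' Run the full per-subject pipeline
#'
#' Preprocesses each segment (anti-aliasing, offset correction), detects
#' the peak-systolic frame, and computes every haemodynamic metric:
#' area-weighted mean aortic WSS, LVOT peak velocity, LVOT/aortic kinetic
#' energy density at peak systole, AV/MV forward and backward flow,
#' simplified-Bernoulli gradients over systole, and LVOT longitudinal
#' strain. Supplied masks take precedence; when a segment mask is absent a
#' threshold segmentation of the PC-MRA stands in.
#'
#' @param subject One subject of a [make_cohort()] cohort (or a list with
#'   the same layout).
#' @param config An [analysis_config()].
#' @return One-row data.frame (a subject result).
#' @export
analyze_subject <- function(subject, config = analysis_config()) {
  res <- data.frame(group = subject$group %||% NA_character_,
                    id = subject$id %||% NA_integer_)
  segs <- subject$segments

  seg_metrics <- function(ph, name) {
    pp <- preprocess_field(ph$field, config,
                           static_mask = ph$masks$static_tissue)
    mask <- ph$masks[[name]]
    if (is.null(mask)) {
      pc <- compute_pcmra(ph$magnitude, pp$field)
      mask <- segment_threshold(pc, config$pcmra_threshold_frac)
    }
    lv <- ph$masks$lv %||% mask
    pk <- find_peak_systole(pp$field, lv)
    list(field = pp$field, mask = mask, peak = pk)
  }

  if (!is.null(segs$aorta)) {
    m <- seg_metrics(segs$aorta, "aorta")
    surf <- extract_wall_surface(m$mask, m$field$spacing,
                                 flow_mask = segs$aorta$masks$lumen,
                                 smooth_sigma = config$wss_smooth_sigma)
    res$wss_aorta <- compute_wss(m$field, m$peak, surf, config)$summary
    res$ke_aorta <- kinetic_energy_density(m$field, m$peak, m$mask, config)
    res$peak_systole_frame_aorta <- m$peak
    if (!is.null(subject$tracks$av)) {
      fl <- transvalvular_flow(m$field, subject$tracks$av)
      res$av_forward <- fl$forward
      res$av_backward <- fl$backward
    }
  }
  if (!is.null(segs$lvot)) {
    m <- seg_metrics(segs$lvot, "lvot")
    res$peak_velocity_lvot <- peak_velocity(m$field, m$peak, m$mask)
    res$ke_lvot <- kinetic_energy_density(m$field, m$peak, m$mask, config)
    res$peak_systole_frame <- m$peak
    vser <- peak_velocity_series(m$field, m$mask)
    bg <- bernoulli_gradient(vser, segs$lvot$spec$systole_frames)
    res$dp_mean <- bg$dp_mean
    res$dp_max <- bg$dp_max
    if (!is.null(subject$tracks$mv)) {
      fl <- transvalvular_flow(m$field, subject$tracks$mv)
      res$mv_forward <- fl$forward
      res$mv_backward <- fl$backward
    }
    if (!is.null(subject$contour_lengths)) {
      res$strain_lvot <- longitudinal_strain(subject$contour_lengths)
    }
  }
  res
}
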