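# Calibrated synthetic cohorts: per-subject phantom pairs (LVOT + ascending
# aorta) whose analytic ground truths realise published group statistics.

#' Reference group targets
#'
#' The published group means and SDs used to calibrate synthetic cohorts:
#' aortic wall shear stress (Pa), LVOT and aortic peak kinetic energy
#' density (printed mJ/m3 scale), LVOT peak velocity (m/s), aortic- and
#' mitral-valve forward flow (ml/beat) and LVOT longitudinal strain (%),
#' for three groups of three subjects (isolated myectomy, myectomy with
#' anterior mitral valve leaflet extension, healthy controls).
#'
#' @param path Optional CSV overriding the bundled table (same columns).
#' @return A data.frame, one row per group.
#' @export
reference_group_targets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "group_targets.csv",
                        package = "hemoflow4d", mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Moment-matched seeded draws: n values with sample mean exactly m and
# sample SD exactly s (n >= 2), resampled until all positive when
# truncate = TRUE. For n = 1 or s = 0 the values equal m. When `u` (a
# normalised deviation vector, mean 0, SD 1) is given it is used directly,
# so several metrics can share one latent per-subject severity factor.
draw_targets <- function(m, s, n, truncate = TRUE, u = NULL) {
  if (n == 1 || s == 0) return(rep(m, n))
  if (!is.null(u)) {
    x <- m + s * u
    if (truncate && any(x <= 0)) {
      stop("could not draw positive targets for mean ", m, ", sd ", s,
           call. = FALSE)
    }
    return(x)
  }
  for (i in 1:50) {
    z <- stats::rnorm(n)
    if (stats::sd(z) < 1e-9) next
    x <- m + s * (z - mean(z)) / stats::sd(z)
    if (!truncate || all(x > 0)) return(x)
  }
  stop("could not draw positive targets for mean ", m, ", sd ", s,
       call. = FALSE)
}

# Normalised deviations (sample mean 0, sample SD 1) for n subjects.
draw_deviations <- function(n) {
  if (n == 1) return(0)
  for (i in 1:50) {
    z <- stats::rnorm(n)
    if (stats::sd(z) > 1e-9) return((z - mean(z)) / stats::sd(z))
  }
  stop("degenerate deviation draw", call. = FALSE)
}

# Shape the waveform so the per-beat forward volume equals sv_ml, keeping
# the systolic peak amplitude (and hence peak-frame WSS/KE/velocity) fixed.
# The systolic lobe exponent alpha is solved first; targets beyond the
# systolic capacity add a diastolic forward lobe of amplitude beta.
waveform_for_sv <- function(sv_ml, vmax, n, radius, n_frames = 24L,
                            systole_frames = 2:10, rr_interval = 1000) {
  dt_s <- rr_interval / n_frames / 1000
  per_unit <- pi * radius^2 * vmax * n / (n + 2) * dt_s  # ml per unit sum(w)
  s_needed <- sv_ml / per_unit
  ssum <- function(alpha) sum(systolic_waveform(n_frames, systole_frames,
                                                alpha = alpha))
  lo <- 0.2; hi <- 8
  if (s_needed >= ssum(lo)) {
    alpha <- lo
    w1 <- systolic_waveform(n_frames, systole_frames, alpha = alpha, beta = 1)
    cap <- sum(w1) - ssum(alpha)                 # diastolic capacity at beta 1
    beta <- (s_needed - ssum(alpha)) / cap
    if (beta > 1.5) {
      stop(sprintf(paste0("infeasible stroke-volume target %.1f ml: needs ",
                          "diastolic amplitude %.2f x systolic peak (cap 1.5)"),
                   sv_ml, beta), call. = FALSE)
    }
  } else if (s_needed <= ssum(hi)) {
    stop(sprintf("infeasible stroke-volume target %.1f ml: below minimum %.1f ml",
                 sv_ml, ssum(hi) * per_unit), call. = FALSE)
  } else {
    alpha <- stats::uniroot(function(a) ssum(a) - s_needed, c(lo, hi),
                            tol = 1e-10)$root
    beta <- 0
  }
  vmax * systolic_waveform(n_frames, systole_frames, alpha = alpha, beta = beta)
}

# Aortic radius (m) at which (wss, ke) targets admit a profile exponent
# n >= 1, times a 10% safety factor; at least radius_mm.
feasible_radius <- function(wss, ke, radius_mm, config) {
  rmin <- config$mu * sqrt(12 * ke / config$rho) / wss * 1000
  max(radius_mm, 1.1 * rmin)
}

#' Generate a calibrated synthetic cohort
#'
#' Builds `n_subjects` subjects for one group. Per-subject targets are
#' drawn from the group mean/SD (seeded, moment-matched so the cohort
#' realises the printed mean and SD exactly, truncated at 0), then each
#' subject gets up to two independent tube phantoms: an LVOT segment
#' (radius `lvot_radius`; centreline velocity = the peak-velocity target,
#' exponent solved from the KE target) and an ascending-aorta segment
#' (exponent and velocity solved from the WSS and KE targets via
#' [calibrate_segment()]; the radius grows above `aorta_radius` when the
#' targets require it). Valve-flow targets (AV on the aorta, MV on the
#' LVOT) are realised by shaping the waveform area. Tube axes are oblique
#' to the grid and centres are jittered sub-voxel per subject.
#'
#' @param targets One row of [reference_group_targets()] (or a list with
#'   the same names).
#' @param n_subjects Number of subjects.
#' @param config An [analysis_config()].
#' @param seed Integer seed; the full cohort is reproducible given it.
#' @param noise_frac Velocity noise SD as a fraction of venc.
#' @param segments Which segments to generate ("lvot", "aorta" or both).
#' @param lvot_radius,aorta_radius Segment radii in mm.
#' @param offsets Add random second-order background phase offsets?
#' @param alias Enable venc wrap-around?
#' @return List of class `flow_cohort`: `subjects` (each with `group`,
#'   `id`, `segments`, `tracks`, `contour_lengths`, `targets`) plus the
#'   drawn `target_table`.
#' @export
make_cohort <- function(targets, n_subjects = 3, config = analysis_config(),
                        seed = 1L, noise_frac = 0.02,
                        segments = c("lvot", "aorta"),
                        lvot_radius = 9.4, aorta_radius = 12.5,
                        offsets = TRUE, alias = TRUE) {
  if (n_subjects < 1) stop("need n_subjects >= 1", call. = FALSE)
  targets <- as.list(targets)
  segments <- match.arg(segments, several.ok = TRUE)
  set.seed(seed)
  tv <- function(nm, positive = TRUE) {
    v <- targets[[nm]]
    if (is.null(v) || !is.finite(v)) {
      stop("missing target value: ", nm, call. = FALSE)
    }
    if (positive && v <= 0 && !grepl("_sd$", nm)) {
      stop("non-positive target: ", nm, call. = FALSE)
    }
    v
  }
  draw <- function(nm, truncate = TRUE, u = NULL) {
    draw_targets(tv(nm, positive = truncate), tv(paste0(nm, "_sd"), FALSE),
                 n_subjects, truncate = truncate, u = u)
  }
  # one latent severity factor drives the haemodynamic metrics (within a
  # group, peak velocity, KE and WSS co-vary with flow vigor; independent
  # draws routinely demand profile exponents outside [1, 20]); stroke
  # volumes get their own factor. Resample on residual infeasibility.
  tt <- data.frame(subject = seq_len(n_subjects))
  ok <- FALSE
  for (attempt in 1:10) {
    u_sev <- draw_deviations(n_subjects)
    u_sv <- draw_deviations(n_subjects)
    feasible <- TRUE
    if ("aorta" %in% segments) {
      tt$wss_aorta <- draw("wss_aorta", u = u_sev)
      tt$ke_aorta <- draw("ke_aorta", u = u_sev)
      tt$av_forward <- draw("av_forward", u = u_sv)
      feasible <- feasible && all(tt$wss_aorta > 0 & tt$ke_aorta > 0)
    }
    if ("lvot" %in% segments) {
      tt$vpeak_lvot <- draw("vpeak_lvot", u = u_sev)
      tt$ke_lvot <- draw("ke_lvot", u = u_sev)
      tt$mv_forward <- draw("mv_forward", u = u_sv)
      G <- 2 * tt$ke_lvot / (config$rho * tt$vpeak_lvot^2)
      feasible <- feasible && all(tt$vpeak_lvot > 0 & tt$ke_lvot > 0 &
                                    G > ke_shape_factor(1) &
                                    G < ke_shape_factor(20))
    }
    if (feasible) {
      ok <- TRUE
      break
    }
  }
  if (!ok) {
    stop("infeasible subject targets after 10 resamples for group '",
         targets$group %||% "?", "': the drawn (velocity, KE, WSS) ",
         "combinations admit no profile exponent in [1, 20]", call. = FALSE)
  }
  if ("lvot" %in% segments && !is.null(targets$strain_lvot)) {
    tt$strain_lvot <- draw("strain_lvot", truncate = FALSE)
  }

  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    segs <- list()
    tracks <- list()
    jitter <- stats::runif(2, -1.2, 1.2)
    ax <- c(0.15 + stats::runif(1, -0.05, 0.05),
            0.09 + stats::runif(1, -0.05, 0.05), 1)
    sub_seed <- function(k) (seed * 131L + i * 17L + k) %% .Machine$integer.max

    if ("lvot" %in% segments) {
      cal <- calibrate_lvot(tt$vpeak_lvot[i], tt$ke_lvot[i], config)
      wf <- waveform_for_sv(tt$mv_forward[i], cal$vmax, cal$n, lvot_radius)
      sp <- phantom_spec(radius = lvot_radius, profile_exponent = cal$n,
                         vmax_waveform = wf, noise_frac = noise_frac,
                         offset_coeffs = if (offsets) random_offsets() else NULL,
                         alias = alias, axis = ax, center_offset = jitter,
                         segment = "lvot", seed = sub_seed(1L))
      segs$lvot <- make_tube_phantom(sp, config)
      tracks$mv <- inlet_track(segs$lvot)
    }
    if ("aorta" %in% segments) {
      r_mm <- feasible_radius(tt$wss_aorta[i], tt$ke_aorta[i], aorta_radius,
                              config)
      cal <- calibrate_segment(tt$wss_aorta[i], tt$ke_aorta[i], r_mm / 1000,
                               config)
      wf <- waveform_for_sv(tt$av_forward[i], cal$vmax, cal$n, r_mm)
      sp <- phantom_spec(radius = r_mm, profile_exponent = cal$n,
                         vmax_waveform = wf, noise_frac = noise_frac,
                         offset_coeffs = if (offsets) random_offsets() else NULL,
                         alias = alias, axis = ax, center_offset = jitter,
                         segment = "aorta", seed = sub_seed(2L))
      segs$aorta <- make_tube_phantom(sp, config)
      tracks$av <- inlet_track(segs$aorta)
    }

    contour <- NULL
    if (!is.null(tt$strain_lvot) && "lvot" %in% segments) {
      w <- segs$lvot$spec$vmax_waveform
      contour <- 50 * (1 + tt$strain_lvot[i] / 100 * w / max(w))
    }
    subjects[[i]] <- list(group = targets$group %||% "group", id = i,
                          segments = segs, tracks = tracks,
                          contour_lengths = contour,
                          targets = as.list(tt[i, -1, drop = FALSE]))
  }
  structure(list(subjects = subjects, target_table = tt,
                 group = targets$group %||% "group"),
            class = "flow_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# LVOT calibration: centreline velocity equals the peak-velocity target;
# the exponent n solves g(n) = 2 ke / (rho vpeak^2), resampling is the
# caller's job (g is increasing on [1, 20] from 1/6 to ~0.87).
calibrate_lvot <- function(vpeak, ke, config, lo = 1, hi = 20) {
  G <- 2 * ke / (config$rho * vpeak^2)
  if (G < ke_shape_factor(lo) || G > ke_shape_factor(hi)) {
    stop(sprintf(paste0("infeasible LVOT target: needs profile shape factor ",
                        "g(n) = %.3f outside [g(1), g(20)] = [%.3f, %.3f]"),
                 G, ke_shape_factor(lo), ke_shape_factor(hi)), call. = FALSE)
  }
  n <- stats::uniroot(function(n) ke_shape_factor(n) - G, c(lo, hi),
                      tol = 1e-10)$root
  list(vmax = vpeak, n = n)
}

# Small random second-order background offsets (m/s): constant ~ 0.02,
# linear ~ 0.01, quadratic/cross ~ 0.005 SD per component.
random_offsets <- function() {
  cbind(stats::rnorm(3, sd = 0.02), matrix(stats::rnorm(9, sd = 0.01), 3),
        matrix(stats::rnorm(18, sd = 0.005), 3))
}

# Static valve plane at the segment inlet: origin on the tube axis just
# upstream of the analysis segment, normal along the axis, aperture wide
# enough to cover the lumen.
inlet_track <- function(phantom) {
  sp <- phantom$spec
  geo <- tube_geometry(sp)
  s_in <- -(sp$length / 2) + 1
  origin <- geo$ctr + s_in * geo$u
  valve_plane_track(n_frames = sp$n_frames, origin = origin, normal = geo$u,
                    radius = sp$radius + 2)
}
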