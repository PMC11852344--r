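# Mask production from PC-MRA, wall-surface extraction and peak-systole
# timing.

#' Threshold segmentation of a PC-MRA
#'
#' Keeps voxels at or above `frac` of the PC-MRA maximum, then the largest
#' 26-connected component only.
#'
#' @param pcmra A `pcmra` (see [compute_pcmra()]).
#' @param frac Threshold as a fraction of the maximum, in (0, 1).
#' @return Logical 3-D mask.
#' @export
segment_threshold <- function(pcmra, frac = 0.5) {
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)", call. = FALSE)
  thr <- pcmra$data >= frac * max(pcmra$data)
  if (!any(thr)) stop("segmentation error: empty mask", call. = FALSE)
  largest_component_26(thr)
}

# Largest 26-connected component of a logical 3-D array.
largest_component_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) stop("segmentation error: empty mask", call. = FALSE)
  coord <- arrayInd(idx, d)
  id <- integer(prod(d))
  id[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 |
           (offs[, 1] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 3] > 0)))), ,
           drop = FALSE]                       # 13 unique positive directions
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- coord + matrix(offs[k, ], nrow(coord), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
    hit <- id[nb_lin] > 0
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(ok)[hit], id[nb_lin[hit]]))
    }
  }
  if (is.null(edges)) return(array(seq_len(prod(d)) == idx[1], d))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE) +
    igraph::vertices(setdiff(seq_along(idx), unique(as.vector(edges))))
  comp <- igraph::components(g)
  keep <- comp$membership[seq_along(idx)] == which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx[keep]] <- TRUE
  out
}

#' Wall surface of a segmentation mask
#'
#' Surface points with inward unit normals and per-point area weights, for
#' wall shear stress evaluation. Points start at the centres of exposed
#' voxel faces (the 0.5 iso-surface of the binary mask) and are projected
#' onto the 0.5 level set of the Gaussian-smoothed mask, with a curvature
#' correction (outward shift `sigma^2 kappa / 2`) for the level-set erosion
#' that smoothing inflicts on convex shapes; total displacement is capped
#' at one voxel. Normals come from the smoothed-mask gradient; each face
#' contributes area weight `A_face |n . e_face|`, whose sum converges to
#' the true surface area.
#'
#' When `flow_mask` is given, exposed faces whose outside neighbour still
#' carries flow (e.g. the open inlet/outlet cross-sections of a vessel
#' segment) are not walls and are excluded.
#'
#' @param mask Logical 3-D array, non-empty, not touching the volume border.
#' @param spacing Voxel size in mm, length 3.
#' @param flow_mask Optional logical 3-D array of the full flow region.
#' @param smooth_sigma Gaussian sigma in mm for normal estimation.
#' @return Object of class `wall_surface`: `points` (N x 3, mm),
#'   `inward_normals` (N x 3, unit), `area_weights` (mm2).
#' @export
extract_wall_surface <- function(mask, spacing, flow_mask = NULL,
                                 smooth_sigma = 2.8) {
  d <- dim(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
      any(mask[, , c(1, d[3])])) {
    stop("border error: mask touches the volume border; pad the volume first",
         call. = FALSE)
  }
  sm <- gaussian_smooth3(mask + 0, smooth_sigma, spacing)
  g <- gradient3(sm, spacing)
  gn <- sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2)
  # divergence of the inward unit normal field = -(total curvature)
  N <- g / pmax(array(gn, c(d, 3)), 1e-9)
  divN <- array(0, d)
  divN[2:(d[1] - 1), , ] <- divN[2:(d[1] - 1), , ] +
    (N[3:d[1], , , 1] - N[1:(d[1] - 2), , , 1]) / (2 * spacing[1])
  divN[, 2:(d[2] - 1), ] <- divN[, 2:(d[2] - 1), ] +
    (N[, 3:d[2], , 2] - N[, 1:(d[2] - 2), , 2]) / (2 * spacing[2])
  divN[, , 2:(d[3] - 1)] <- divN[, , 2:(d[3] - 1)] +
    (N[, , 3:d[3], 3] - N[, , 1:(d[3] - 2), 3]) / (2 * spacing[3])

  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  idx <- which(mask, arr.ind = TRUE)
  pts <- nrm <- NULL
  wts <- numeric(0)
  for (k in 1:6) {
    o <- offs[k, ]
    nb <- sweep(idx, 2, o, "+")
    nbv <- mask[nb]
    exposed <- !nbv
    if (!is.null(flow_mask)) exposed <- exposed & !flow_mask[nb]
    if (!any(exposed)) next
    vox <- idx[exposed, , drop = FALSE]
    fc <- sweep(vox - 1, 2, spacing, "*") +
      matrix(o * spacing / 2, nrow(vox), 3, byrow = TRUE)
    pv <- sweep(fc, 2, spacing, "/")
    gp <- cbind(interp_trilinear(g[, , , 1], pv)$value,
                interp_trilinear(g[, , , 2], pv)$value,
                interp_trilinear(g[, , , 3], pv)$value)
    nn <- sqrt(rowSums(gp^2))
    flat <- nn < 1e-9
    if (any(flat)) gp[flat, ] <- -matrix(o, sum(flat), 3, byrow = TRUE)
    gp <- gp / sqrt(rowSums(gp^2))
    a_face <- prod(spacing) / spacing[abs(o) == 1]
    w <- a_face * pmax(abs(as.vector(gp %*% o)), 1e-6)
    pts <- rbind(pts, fc)
    nrm <- rbind(nrm, gp)
    wts <- c(wts, w)
  }

  # Newton projection onto the sm = 0.5 level set
  p0 <- pts
  p <- pts
  for (it in 1:4) {
    pv <- sweep(p, 2, spacing, "/")
    smv <- interp_trilinear(sm, pv)$value
    gx <- interp_trilinear(g[, , , 1], pv)$value
    gy <- interp_trilinear(g[, , , 2], pv)$value
    gz <- interp_trilinear(g[, , , 3], pv)$value
    gg <- pmax(sqrt(gx^2 + gy^2 + gz^2), 1e-9)
    step <- pmin(pmax((0.5 - smv) / gg, -2.5), 2.5)
    p <- p + step * cbind(gx, gy, gz) / gg
  }
  pv <- sweep(p, 2, spacing, "/")
  smv <- interp_trilinear(sm, pv)$value
  gx <- interp_trilinear(g[, , , 1], pv)$value
  gy <- interp_trilinear(g[, , , 2], pv)$value
  gz <- interp_trilinear(g[, , , 3], pv)$value
  gg <- pmax(sqrt(gx^2 + gy^2 + gz^2), 1e-9)
  n_in <- cbind(gx, gy, gz) / gg
  # curvature correction for level-set erosion of convex shapes
  kappa <- -interp_trilinear(divN, pv)$value   # total curvature, outward sense
  delta <- pmin(pmax(smooth_sigma^2 / 2 * kappa, -2), 2)
  p <- p - delta * n_in
  # keep points within one voxel of the binary boundary; revert failures
  disp <- p - p0
  dd <- sqrt(rowSums(disp^2))
  cap <- max(spacing)
  far <- dd > cap
  p[far, ] <- p0[far, ] + disp[far, , drop = FALSE] * (cap / dd[far])
  bad <- abs(smv - 0.5) > 0.2
  p[bad, ] <- p0[bad, , drop = FALSE]
  n_in[bad, ] <- nrm[bad, , drop = FALSE]

  structure(list(points = p, inward_normals = n_in, area_weights = wts),
            class = "wall_surface")
}

#' @export
print.wall_surface <- function(x, ...) {
  cat(sprintf("<wall_surface> %d points, total area %.1f mm2\n",
              nrow(x$points), sum(x$area_weights)))
  invisible(x)
}

#' Peak-systolic frame
#'
#' The cardiac frame with the highest mean speed inside the left-ventricle
#' mask, restricted to the first half of the cycle (frames 1..ceiling(T/2),
#' 1-based); ties resolve to the earliest frame.
#'
#' @param field A [velocity_field()].
#' @param lv_mask Logical 3-D mask, non-empty.
#' @return Integer frame index (1-based).
#' @export
find_peak_systole <- function(field, lv_mask) {
  check_mask_grid(lv_mask, field)
  if (!any(lv_mask)) stop("lv mask is empty", call. = FALSE)
  half <- ceiling(field$n_frames / 2)
  sp <- speed_array(field)
  means <- vapply(seq_len(half),
                  function(t) mean(sp[, , , t][lv_mask]), numeric(1))
  which.max(means)
}
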