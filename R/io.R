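#' Write a velocity field (plus optional magnitude and masks) to HDF5
#'
#' Single-file container: dataset `velocity` with dim (x, y, z, t, 3),
#' optional `magnitude` (x, y, z, t) and one uint8 volume per mask, with
#' attributes `spacing_mm`, `frame_duration_ms`, `venc_ms`, `rr_ms` on the
#' velocity dataset. Values are stored as float64, so read and write
#' round-trip bit-exactly.
#'
#' @param field A [velocity_field()].
#' @param path Output `.h5` file path (overwritten if present).
#' @param magnitude Optional [magnitude_series()].
#' @param masks Optional [mask_set()].
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path, magnitude = NULL, masks = NULL) {
  validate_velocity_field(field)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stop("cannot write to ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(field$data, path, "velocity")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "velocity")
  rhdf5::h5writeAttribute(field$spacing, did, "spacing_mm")
  rhdf5::h5writeAttribute(field$frame_duration, did, "frame_duration_ms")
  rhdf5::h5writeAttribute(field$venc, did, "venc_ms")
  rhdf5::h5writeAttribute(field$rr_interval, did, "rr_ms")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  if (!is.null(magnitude)) rhdf5::h5write(magnitude$data, path, "magnitude")
  if (!is.null(masks)) {
    for (nm in names(masks)) {
      if (!is.null(masks[[nm]])) {
        rhdf5::h5write(array(as.integer(masks[[nm]]), dim(masks[[nm]])),
                       path, paste0("mask_", nm))
      }
    }
  }
  invisible(path)
}

#' Read a velocity field container written by [write_velocity_field()]
#'
#' @param path Path to the `.h5` container.
#' @return A list with `field` ([velocity_field()]) and, when present in the
#'   file, `magnitude` and `masks`.
#' @export
read_velocity_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  if (!"velocity" %in% contents$name) {
    stop("format error: no 'velocity' dataset in ", path, call. = FALSE)
  }
  data <- rhdf5::h5read(path, "velocity")
  att <- rhdf5::h5readAttributes(path, "velocity")
  need <- c("spacing_mm", "frame_duration_ms", "venc_ms", "rr_ms")
  missing <- setdiff(need, names(att))
  if (length(missing) > 0) {
    stop("format error: missing metadata attribute(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  field <- velocity_field(data,
                          spacing = as.numeric(att$spacing_mm),
                          frame_duration = as.numeric(att$frame_duration_ms),
                          venc = as.numeric(att$venc_ms),
                          rr_interval = as.numeric(att$rr_ms))
  out <- list(field = field)
  if ("magnitude" %in% contents$name) {
    out$magnitude <- magnitude_series(rhdf5::h5read(path, "magnitude"))
  }
  mask_names <- grep("^mask_", contents$name, value = TRUE)
  if (length(mask_names) > 0) {
    masks <- list()
    for (nm in mask_names) {
      masks[[sub("^mask_", "", nm)]] <- array(rhdf5::h5read(path, nm) > 0,
                                              grid_dim(field))
    }
    out$masks <- do.call(mask_set, masks[intersect(
      c("lv", "lvot", "aorta", "static_tissue", "lumen"), names(masks))])
  }
  out
}

#' Export a velocity field as NIfTI volumes
#'
#' One 4-D `.nii.gz` per velocity component (`vx`, `vy`, `vz`), voxel grid
#' authoritative (world coordinates are not used). A JSON sidecar carries
#' the timing metadata that NIfTI headers cannot.
#'
#' @param field A [velocity_field()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
export_nifti <- function(field, dir, prefix = "velocity") {
  validate_velocity_field(field)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comp <- c("vx", "vy", "vz")
  files <- character(0)
  for (c in 1:3) {
    img <- RNifti::asNifti(field$data[, , , , c],
                           pixdim = c(field$spacing, field$frame_duration))
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, comp[c]))
    RNifti::writeNifti(img, f, datatype = "double")
    files <- c(files, f)
  }
  meta <- list(spacing_mm = field$spacing,
               frame_duration_ms = field$frame_duration,
               venc_ms = field$venc, rr_ms = field$rr_interval)
  mf <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

#' Import a velocity field from NIfTI volumes written by [export_nifti()]
#'
#' @param dir Directory holding the component volumes and JSON sidecar.
#' @param prefix File name prefix used at export.
#' @return A [velocity_field()].
#' @export
import_nifti <- function(dir, prefix = "velocity") {
  mf <- file.path(dir, paste0(prefix, "_meta.json"))
  if (!file.exists(mf)) stop("format error: missing sidecar ", mf, call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  comp <- c("vx", "vy", "vz")
  vols <- lapply(comp, function(cc) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, cc))
    if (!file.exists(f)) stop("format error: missing component file ", f,
                              call. = FALSE)
    as.array(RNifti::readNifti(f))
  })
  d <- dim(vols[[1]])
  data <- array(0, c(d, 3))
  for (c in 1:3) data[, , , , c][] <- vols[[c]]
  velocity_field(data, spacing = meta$spacing_mm,
                 frame_duration = meta$frame_duration_ms,
                 venc = meta$venc_ms, rr_interval = meta$rr_ms)
}

#' Export a 3-D scalar volume (e.g. a PC-MRA or a mask) as NIfTI
#'
#' @param vol 3-D numeric or logical array.
#' @param spacing Voxel size in mm, length 3.
#' @param path Output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
export_volume_nifti <- function(vol, spacing, path) {
  img <- RNifti::asNifti(vol + 0, pixdim = spacing)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
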