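#' Analysis configuration
#'
#' Physical constants and tunable parameters shared by the whole pipeline.
#' Dynamic viscosity and density default to standard blood values
#' (mu = 3.2e-3 Pa s, rho = 1060 kg/m3).
#'
#' @param mu Dynamic blood viscosity in Pa s.
#' @param rho Blood density in kg/m3.
#' @param pcmra_threshold_frac Fraction of the PC-MRA maximum used by
#'   threshold segmentation, in (0, 1).
#' @param static_sd_frac Fraction of venc below which both the temporal
#'   speed SD and the temporal mean speed classify a voxel as static tissue.
#' @param wss_sample_distances Distances in mm along the inward surface
#'   normal at which velocity is sampled for the wall shear stress fit.
#' @param wss_smooth_sigma Gaussian sigma in mm used to smooth the binary
#'   mask for surface normal estimation and point projection.
#' @param ci_level Confidence level for cohort tables, in (0, 1).
#' @param seed Integer random seed.
#'
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(mu = 0.0032,
                            rho = 1060,
                            pcmra_threshold_frac = 0.5,
                            static_sd_frac = 0.05,
                            wss_sample_distances = c(1.2, 1.8, 2.4),
                            wss_smooth_sigma = 2.8,
                            ci_level = 0.95,
                            seed = 1L) {
  cfg <- list(
    mu = mu, rho = rho,
    pcmra_threshold_frac = pcmra_threshold_frac,
    static_sd_frac = static_sd_frac,
    wss_sample_distances = wss_sample_distances,
    wss_smooth_sigma = wss_smooth_sigma,
    ci_level = ci_level,
    seed = as.integer(seed)
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop(sprintf("invalid config value for '%s': %s", key, what),
                  call. = FALSE)
  }
  chk(is.numeric(cfg$mu) && cfg$mu > 0, "mu", "must be > 0")
  chk(is.numeric(cfg$rho) && cfg$rho > 0, "rho", "must be > 0")
  chk(cfg$pcmra_threshold_frac > 0 && cfg$pcmra_threshold_frac < 1,
      "pcmra_threshold_frac", "must be in (0, 1)")
  chk(cfg$static_sd_frac > 0, "static_sd_frac", "must be > 0")
  chk(length(cfg$wss_sample_distances) >= 2 &&
        all(cfg$wss_sample_distances > 0) &&
        !any(duplicated(cfg$wss_sample_distances)),
      "wss_sample_distances", "needs >= 2 distinct positive distances (mm)")
  chk(cfg$wss_smooth_sigma > 0, "wss_smooth_sigma", "must be > 0")
  chk(cfg$ci_level > 0 && cfg$ci_level < 1, "ci_level", "must be in (0, 1)")
  chk(is.finite(cfg$seed), "seed", "must be a finite integer")
  cfg
}

#' Load an analysis configuration from a YAML or JSON file
#'
#' Keys absent from the file keep their defaults; unknown keys raise an
#' error; out-of-range values raise a validation error naming the key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` key-value file.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-22s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
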