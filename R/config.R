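#' Run configuration
#'
#' Collects the tunable parameters of the beamforming and analysis pipeline
#' with validation. Defaults follow the caprine linear-array acquisition
#' preset; [preset_config()] returns the named parameter sets used throughout.
#'
#' @param M SLSC lag cutoff (integer, `1 <= M <= n_lags`).
#' @param n_lags total number of lags retained in the coherence stack
#'   (`N_L`); must be smaller than the element count at use time.
#' @param axial_kernel_wavelengths axial correlation-kernel length in
#'   wavelengths (converted to samples at use time).
#' @param kernel_lateral_mm,kernel_axial_mm LW-SLSC moving-kernel size in mm.
#' @param overlap LW-SLSC kernel overlap fraction in `[0, 1)`.
#' @param alpha LW-SLSC regularization factor (>= 0) applied to the
#'   lag-gradient penalty.
#' @param threshold segmentation threshold as a fraction of the image maximum
#'   in `(0, 1)`.
#' @param open_mm,close_mm morphological structuring-element sizes in mm.
#' @param roi_mm side length of the square target ROI in mm.
#' @param background_offset_mm axial offset of the background ROI centre
#'   above the target centre, in mm.
#' @param snr_threshold frames with SNR at or below this value are discarded
#'   as out-of-plane.
#' @param dynamic_range_db display dynamic range in dB.
#' @param seed integer seed recorded with the run.
#' @param out_dir default output directory.
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(M = 9, n_lags = 28, axial_kernel_wavelengths = 2,
                       kernel_lateral_mm = 1.20, kernel_axial_mm = 1.92,
                       overlap = 0.5, alpha = 0.12,
                       threshold = 0.5, open_mm = 0.38, close_mm = 0.63,
                       roi_mm = 10, background_offset_mm = 25,
                       snr_threshold = 3, dynamic_range_db = 25,
                       seed = 0L, out_dir = ".") {
  cfg <- list(M = as.integer(M), n_lags = as.integer(n_lags),
              axial_kernel_wavelengths = axial_kernel_wavelengths,
              kernel_lateral_mm = kernel_lateral_mm,
              kernel_axial_mm = kernel_axial_mm,
              overlap = overlap, alpha = alpha, threshold = threshold,
              open_mm = open_mm, close_mm = close_mm, roi_mm = roi_mm,
              background_offset_mm = background_offset_mm,
              snr_threshold = snr_threshold,
              dynamic_range_db = dynamic_range_db,
              seed = as.integer(seed), out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  bad <- function(key, why) {
    stop(sprintf("run_config: invalid '%s': %s", key, why), call. = FALSE)
  }
  if (cfg$alpha < 0) bad("alpha", "must be >= 0")
  if (!(cfg$overlap >= 0 && cfg$overlap < 1)) bad("overlap", "must lie in [0, 1)")
  if (cfg$M < 1 || cfg$M > cfg$n_lags) bad("M", "must satisfy 1 <= M <= n_lags")
  if (cfg$n_lags < 2) bad("n_lags", "must be >= 2")
  if (!(cfg$threshold > 0 && cfg$threshold < 1)) bad("threshold", "must lie in (0, 1)")
  if (cfg$axial_kernel_wavelengths <= 0) bad("axial_kernel_wavelengths", "must be > 0")
  if (cfg$open_mm <= 0 || cfg$close_mm <= 0) bad("open_mm/close_mm", "must be > 0")
  if (cfg$roi_mm <= 0) bad("roi_mm", "must be > 0")
  if (cfg$dynamic_range_db <= 0) bad("dynamic_range_db", "must be > 0")
  invisible(cfg)
}

#' Named parameter presets
#'
#' Two acquisition presets are shipped. `"caprine"` matches a 128-element
#' linear-array acquisition (SLSC `M = 9`, 2-wavelength axial kernel;
#' LW-SLSC 1.20 mm x 1.92 mm kernel, 50% overlap, `N_L = 28`, `alpha = 0.12`).
#' `"cadaver_us"` and `"cadaver_pa"` match the convex-array cadaver settings
#' (ultrasound: `M = 5`, 1-wavelength kernel, `N_L = 15`, 2.0 mm x 3.1 mm,
#' 60% overlap, `alpha = 1`; photoacoustic: `M = 15`, `N_L = 25`, otherwise
#' identical).
#'
#' @param name one of `"caprine"`, `"cadaver_us"`, `"cadaver_pa"`.
#' @param ... overrides forwarded to [run_config()].
#' @return A [run_config()].
#' @export
preset_config <- function(name = c("caprine", "cadaver_us", "cadaver_pa"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    caprine = list(M = 9, n_lags = 28, axial_kernel_wavelengths = 2,
                   kernel_lateral_mm = 1.20, kernel_axial_mm = 1.92,
                   overlap = 0.5, alpha = 0.12, threshold = 0.5),
    cadaver_us = list(M = 5, n_lags = 15, axial_kernel_wavelengths = 1,
                      kernel_lateral_mm = 2.0, kernel_axial_mm = 3.1,
                      overlap = 0.6, alpha = 1, threshold = 0.3),
    cadaver_pa = list(M = 15, n_lags = 25, axial_kernel_wavelengths = 1,
                      kernel_lateral_mm = 2.0, kernel_axial_mm = 3.1,
                      overlap = 0.6, alpha = 1, threshold = 0.3))
  do.call(run_config, utils::modifyList(base, list(...)))
}

#' Load / save a configuration as YAML
#'
#' Absent keys take [run_config()] defaults; all values are validated on
#' load, so `load_config(save_config(cfg))` is idempotent.
#'
#' @param path YAML file path.
#' @param cfg a [run_config()].
#' @return `load_config()` a [run_config()]; `save_config()` `path`, invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
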