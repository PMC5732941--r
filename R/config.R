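# Detection configuration and the published per-sample-type parameter presets

#' Detection parameters
#'
#' Bundles all tunable parameters of the detection pipeline. Spatial
#' parameters are in voxel units and may be given per axis (z, y, x) for
#' anisotropic data.
#'
#' @param sigma_low standard deviation (voxels) of the low-pass Gaussian of
#'   the band-pass filter; scalar or per-axis. Should exceed the typical
#'   noise-artifact radius and stay below the cell radius.
#' @param sigma_high standard deviation (voxels) of the high-pass Gaussian;
#'   scalar or per-axis. Should exceed the cell radius by roughly 1.5-2x.
#' @param threshold_fraction fraction in \[0, 1\] of the maximal band-passed
#'   intensity below which voxels are zeroed (typically 0.05-0.10).
#' @param min_segment_voxels segments smaller than this are discarded as
#'   sub-cellular fragments (typically 10-100).
#' @param fit_radius radius (voxels) around each segment peak whose voxels
#'   enter the Gaussian fit.
#' @param bootstrap_iters number of bootstrap resamples per segment.
#' @param std_min,std_max acceptance bounds (voxels) on every fitted
#'   principal standard deviation; `std_max` may be `Inf`.
#' @param amp_min,amp_max optional acceptance bounds on the fitted amplitude,
#'   unbounded by default.
#' @param p_threshold segments with bootstrap p-value below this are reported
#'   as cells.
#' @param rng_seed integer seed for the bootstrap resampling.
#' @param reference_histogram optional path to a reference histogram CSV used
#'   to normalize volumes before detection (see
#'   [write_reference_histogram()]).
#' @param background_volume optional path to a co-registered
#'   autofluorescence channel to subtract.
#' @return An object of class `detection_config`.
#' @seealso [detection_preset()] for published per-sample-type settings.
#' @export
detection_config <- function(sigma_low = 0.4, sigma_high = 10,
                             threshold_fraction = 0.1,
                             min_segment_voxels = 10L, fit_radius = 7,
                             bootstrap_iters = 1000L,
                             std_min = 1.5, std_max = Inf,
                             amp_min = 0, amp_max = Inf,
                             p_threshold = 0.01, rng_seed = 1L,
                             reference_histogram = NULL,
                             background_volume = NULL) {
  cfg <- list(
    sigma_low = as_triple(sigma_low, "sigma_low"),
    sigma_high = as_triple(sigma_high, "sigma_high"),
    threshold_fraction = as.numeric(threshold_fraction),
    min_segment_voxels = as.integer(min_segment_voxels),
    fit_radius = as.numeric(fit_radius),
    bootstrap_iters = as.integer(bootstrap_iters),
    std_min = as.numeric(std_min), std_max = as.numeric(std_max),
    amp_min = as.numeric(amp_min), amp_max = as.numeric(amp_max),
    p_threshold = as.numeric(p_threshold),
    rng_seed = as.integer(rng_seed),
    reference_histogram = reference_histogram,
    background_volume = background_volume)

  if (any(cfg$sigma_low <= 0) || any(cfg$sigma_low >= cfg$sigma_high))
    c3d_stop("c3d_error_config", "need 0 < sigma_low < sigma_high on every axis")
  if (cfg$threshold_fraction < 0 || cfg$threshold_fraction > 1)
    c3d_stop("c3d_error_config", "threshold_fraction must lie in [0, 1]")
  if (cfg$min_segment_voxels < 1L)
    c3d_stop("c3d_error_config", "min_segment_voxels must be a positive integer")
  if (cfg$fit_radius <= 0)
    c3d_stop("c3d_error_config", "fit_radius must be positive")
  if (cfg$bootstrap_iters < 1L)
    c3d_stop("c3d_error_config", "bootstrap_iters must be a positive integer")
  if (!(cfg$std_min >= 0) || cfg$std_min >= cfg$std_max)
    c3d_stop("c3d_error_config", "need 0 <= std_min < std_max")
  if (cfg$p_threshold < 0 || cfg$p_threshold > 1)
    c3d_stop("c3d_error_config", "p_threshold must lie in [0, 1]")
  structure(cfg, class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  cat(sprintf("  band-pass sigma (voxels): low %s / high %s\n",
              paste(x$sigma_low, collapse = ","),
              paste(x$sigma_high, collapse = ",")))
  cat(sprintf("  threshold: %g%% of max; min segment: %d voxels\n",
              100 * x$threshold_fraction, x$min_segment_voxels))
  cat(sprintf("  fit radius %g, %d bootstrap iterations, stds in [%g, %g], p < %g\n",
              x$fit_radius, x$bootstrap_iters, x$std_min, x$std_max, x$p_threshold))
  invisible(x)
}

# published parameter sets, one per staining/imaging type
preset_table <- list(
  edu_wm = list(sigma_low = 0.4, sigma_high = 10, threshold_fraction = 0.10,
                min_segment_voxels = 10L, std_min = 1.5, std_max = Inf,
                p_threshold = 0.01),
  cfp_wm = list(sigma_low = 0.4, sigma_high = 10, threshold_fraction = 0.05,
                min_segment_voxels = 10L, std_min = 1.5, std_max = Inf,
                p_threshold = 0.01),
  edu_section = list(sigma_low = 2, sigma_high = 6, threshold_fraction = 0.06,
                     min_segment_voxels = 100L, std_min = 4, std_max = 9,
                     p_threshold = 0.3),
  brdu_section = list(sigma_low = 2, sigma_high = 3, threshold_fraction = 0.08,
                      min_segment_voxels = 100L, std_min = 4, std_max = 9,
                      p_threshold = 0.5),
  cfos_section = list(sigma_low = 2, sigma_high = 3, threshold_fraction = 0.04,
                      min_segment_voxels = 100L, std_min = 4, std_max = 9,
                      p_threshold = 0.1),
  dapi_section = list(sigma_low = 2, sigma_high = 6, threshold_fraction = 0.06,
                      min_segment_voxels = 100L, std_min = 4, std_max = 9,
                      p_threshold = 0.3))

#' Published detection parameter presets
#'
#' Returns the detection parameter set used for one of the six validated
#' sample types: EdU- and nestin-CFPnuc-stained whole-mount hippocampi
#' (`edu_wm`, `cfp_wm`) and EdU, BrdU, c-Fos and DAPI stained 50-um tissue
#' sections (`*_section`). All presets use a 7-voxel fit radius and 1000
#' bootstrap iterations. DAPI sections share the EdU section settings.
#'
#' @param name preset name.
#' @param ... overrides passed on to [detection_config()] (e.g. `rng_seed`).
#' @return A [detection_config()].
#' @export
detection_preset <- function(name = names(preset_table), ...) {
  name <- match.arg(name)
  args <- utils::modifyList(preset_table[[name]], list(...))
  do.call(detection_config, args)
}

#' Read / write a detection configuration
#'
#' Configurations are stored as flat YAML key-value files mirroring the
#' arguments of [detection_config()]. A `preset` key may name a
#' [detection_preset()] whose values the remaining keys override.
#'
#' @param path YAML file path.
#' @return [detection_config()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_detection_config <- function(path) {
  if (!file.exists(path))
    c3d_stop("c3d_error_unreadable", "config file '%s' does not exist", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) c3d_stop("c3d_error_config", "config '%s' is not a key-value map", path)
  for (k in c("std_max", "amp_max"))
    if (!is.null(vals[[k]]) && identical(vals[[k]], ".inf")) vals[[k]] <- Inf
  if (!is.null(vals$preset)) {
    preset <- vals$preset
    vals$preset <- NULL
    return(do.call(detection_preset, c(list(name = preset), vals)))
  }
  unknown <- setdiff(names(vals), names(formals(detection_config)))
  if (length(unknown))
    c3d_stop("c3d_error_config", "unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(detection_config, vals)
}

#' @rdname read_detection_config
#' @param config a [detection_config()].
#' @export
write_detection_config <- function(config, path) {
  stopifnot(inherits(config, "detection_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}
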