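# End-to-end detection orchestrator and detection-table I/O.

#' Detect cells in a 3D volume
#'
#' Runs the full detection pipeline:
#' \enumerate{
#'   \item histogram matching against `reference_hist` (if given),
#'   \item autofluorescence subtraction of `background` (if given; the
#'     background channel is histogram-matched to the signal internally),
#'   \item difference-of-Gaussians band-pass filtering,
#'   \item thresholding at `threshold_fraction` of the maximal band-passed
#'     intensity,
#'   \item watershed segmentation of the positive support,
#'   \item removal of segments below `min_segment_voxels`,
#'   \item per-segment bootstrap Gaussian-fit significance testing on the
#'     \emph{unfiltered} (post-step-2) intensities.
#' }
#' Only segments with bootstrap p-value below `config$p_threshold` are
#' returned. The run is fully deterministic given `config$rng_seed`.
#'
#' @param raw the acquired signal channel, a [volume()] with non-negative
#'   intensities.
#' @param config a [detection_config()] or [detection_preset()].
#' @param background optional co-registered autofluorescence channel
#'   ([volume()], same shape).
#' @param reference_hist optional `intensity_histogram` to normalize against.
#' @param quiet suppress per-stage log messages.
#' @return A `detections3d` data frame with one row per detected cell:
#'   0-based voxel centroid (`z`, `y`, `x`), physical centroid
#'   (`z_um`, `y_um`, `x_um`), bootstrap `p_value`, mean principal standard
#'   deviations over passing resamples (`std1` <= `std2` <= `std3`, voxels),
#'   `peak_intensity` (unfiltered), `segment_voxels` and `segment_label`;
#'   rows ordered by `segment_label`. Attributes `n_candidates` (segments
#'   tested) and `n_maxima` (watershed segments before size filtering).
#' @export
detect_cells <- function(raw, config, background = NULL,
                         reference_hist = NULL, quiet = FALSE) {
  raw <- as_volume(raw)
  stopifnot(inherits(config, "detection_config"))
  if (any(raw$data < 0))
    c3d_stop("c3d_error_volume", "raw volume must be non-negative")

  if (is.null(reference_hist) && !is.null(config$reference_histogram))
    reference_hist <- read_reference_histogram(config$reference_histogram)
  if (is.null(background) && !is.null(config$background_volume))
    background <- read_volume(config$background_volume)

  work <- raw
  if (!is.null(reference_hist)) {
    work <- match_histogram(work, reference_hist)
    c3d_log(quiet, "preprocess: histogram matched to reference (%d bins)",
            length(reference_hist$counts))
  }
  if (!is.null(background)) {
    background <- as_volume(background)
    if (!identical(dim(work$data), dim(background$data)))
      c3d_stop("c3d_error_shape_mismatch",
               "background volume shape differs from the signal volume")
    work <- subtract_background_channel(work, background)
    c3d_log(quiet, "preprocess: autofluorescence channel subtracted")
  }

  filtered <- bandpass_filter(work, config$sigma_low, config$sigma_high)
  thresholded <- apply_threshold(filtered, config$threshold_fraction)
  c3d_log(quiet, "preprocess: band-pass + threshold keep %d of %d voxels positive",
          sum(thresholded$data > 0), length(thresholded$data))

  labels <- watershed_segments(thresholded)
  n_maxima <- n_segments(labels)
  labels <- remove_small_segments(labels, config$min_segment_voxels)
  c3d_log(quiet, "segment: %d watershed segments, %d of size >= %d voxels",
          n_maxima, n_segments(labels), config$min_segment_voxels)

  segments <- extract_segments(labels, thresholded)
  det <- classify_segments(work, segments, config, quiet = quiet)
  attr(det, "n_candidates") <- length(segments)
  attr(det, "n_maxima") <- n_maxima
  det
}

#' Write / read a detection table
#'
#' Detections are stored as RFC-4180 CSV with a header row and one row per
#' cell, ordered by `segment_label` (columns: `z,y,x`, `z_um,y_um,x_um`,
#' `p_value`, `std1,std2,std3`, `peak_intensity`, `segment_voxels`,
#' `segment_label`; coordinates 0-based).
#'
#' @param detections a `detections3d` data frame from [detect_cells()].
#' @param path CSV file path.
#' @export
write_detections <- function(detections, path) {
  stopifnot(is.data.frame(detections))
  det <- detections[order(detections$segment_label), , drop = FALSE]
  tryCatch(write.csv(det, path, row.names = FALSE),
           error = function(e)
             c3d_stop("c3d_error_unwritable", "cannot write '%s': %s",
                      path, conditionMessage(e)))
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  if (!file.exists(path))
    c3d_stop("c3d_error_unreadable", "detections file '%s' does not exist", path)
  out <- read.csv(path)
  class(out) <- c("detections3d", "data.frame")
  out
}

#' @export
print.detections3d <- function(x, ...) {
  cat(sprintf("<detections3d> %d cells\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
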