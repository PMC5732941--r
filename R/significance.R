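# Per-segment statistical significance: bootstrap resampling of a
# log-linear 3D Gaussian fit against user-defined cell-size criteria.

#' Cell acceptance criteria for the bootstrap test
#'
#' A segment counts as a cell when the fitted blob's principal standard
#' deviations (and optionally its amplitude) fall inside these bounds.
#'
#' @param std_min,std_max bounds (voxels) on every principal standard
#'   deviation; `std_max` may be `Inf`.
#' @param amp_min,amp_max optional amplitude bounds, unbounded by default.
#' @return An object of class `cell_criteria`.
#' @export
cell_criteria <- function(std_min, std_max = Inf, amp_min = 0, amp_max = Inf) {
  if (!(std_min >= 0) || std_min >= std_max)
    c3d_stop("c3d_error_config", "need 0 <= std_min < std_max")
  if (!(amp_min >= 0) || amp_min >= amp_max)
    c3d_stop("c3d_error_config", "need 0 <= amp_min < amp_max")
  structure(list(std_min = as.numeric(std_min), std_max = as.numeric(std_max),
                 amp_min = as.numeric(amp_min), amp_max = as.numeric(amp_max)),
            class = "cell_criteria")
}

as_criteria <- function(x) {
  if (inherits(x, "cell_criteria")) return(x)
  if (inherits(x, "detection_config"))
    return(cell_criteria(x$std_min, x$std_max, x$amp_min, x$amp_max))
  c3d_stop("c3d_error_config", "expected a cell_criteria or detection_config")
}

#' Collect the voxels entering a segment's Gaussian fit
#'
#' Returns the voxels that belong to the segment AND lie within `radius`
#' voxels (Euclidean) of its intensity peak, as offsets (voxel minus peak)
#' together with their raw (unfiltered) intensities. The radius, typically
#' ~1.5x the cell radius, keeps some local background in the fit while
#' excluding far-away segment tails.
#'
#' @param raw the unfiltered [volume()] (after histogram matching and
#'   background subtraction, before band-pass filtering).
#' @param segment a `segment3d` from [extract_segments()].
#' @param radius inclusion radius in voxels; scalar (sphere) or per-axis
#'   (z, y, x) half-axes of an ellipsoid for anisotropic data.
#' @return A list with `offsets` (n x 3 matrix, voxels), `intensity`
#'   (length-n raw intensities) and `peak` (1-based array index).
#' @export
fit_region_voxels <- function(raw, segment, radius) {
  raw <- as_volume(raw)
  stopifnot(inherits(segment, "segment3d"))
  r3 <- as_triple(radius, "radius")
  if (any(r3 <= 0)) c3d_stop("c3d_error_config", "radius must be positive")
  pk <- segment$peak
  d <- dim(raw$data)
  if (any(pk < 1L) || any(pk > d))
    c3d_stop("c3d_error_config", "segment peak lies outside the volume")
  off <- sweep(segment$voxels, 2, pk)
  keep <- (off[, 1] / r3[1])^2 + (off[, 2] / r3[2])^2 + (off[, 3] / r3[3])^2 <= 1
  if (!any(keep))
    c3d_stop("c3d_error_empty_region", "no segment voxels within the fit radius")
  list(offsets = off[keep, , drop = FALSE],
       intensity = raw$data[segment$lin[keep]],
       peak = pk)
}

#' Fit a 3D Gaussian blob to voxel intensities by log-linear least squares
#'
#' Fits `I(r) = I0 * exp(-1/2 r' S^-1 r)` around the segment peak (offset
#' r = 0 at the peak)
#' by linear regression of `ln I` on the intercept and the six distinct
#' entries of the symmetric inverse-variance matrix `A = S^-1`. Voxels with
#' non-positive intensity cannot enter `ln I` and are excluded. The fit is
#' `valid` only when the regression has full rank and the fitted `A` is
#' positive definite; the principal standard deviations are then
#' `1/sqrt(eigenvalues(A))`, a rotation-invariant description of the blob's
#' half-axis scales.
#'
#' @param offsets n x 3 matrix of (z, y, x) voxel offsets from the peak, or
#'   the list returned by [fit_region_voxels()] (then `intensity` is taken
#'   from it).
#' @param intensity length-n raw intensities.
#' @param min_voxels fits with fewer positive-intensity voxels are invalid.
#' @return An object of class `gaussian_fit`: `amplitude` (I0),
#'   `sigma_matrix` (3x3 variance matrix, voxel^2), `principal_stds`
#'   (ascending, voxels) and `valid`.
#' @export
fit_gaussian <- function(offsets, intensity = NULL, min_voxels = 10L) {
  if (is.list(offsets) && !is.null(offsets$offsets)) {
    intensity <- offsets$intensity
    offsets <- offsets$offsets
  }
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 3L || nrow(offsets) != length(intensity))
    c3d_stop("c3d_error_config", "need an n x 3 offset matrix and n intensities")
  f <- .cpp_fit_gaussian(offsets, as.numeric(intensity), as.integer(min_voxels))
  f$principal_stds <- as.numeric(f$principal_stds)
  structure(f, class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (!x$valid) cat("<gaussian_fit> invalid (rank-deficient or not positive definite)\n")
  else cat(sprintf("<gaussian_fit> I0 = %.4g, principal stds = (%.3g, %.3g, %.3g) voxels\n",
                   x$amplitude, x$principal_stds[1], x$principal_stds[2],
                   x$principal_stds[3]))
  invisible(x)
}

#' Bootstrap significance of one segment
#'
#' Resamples the segment's fit region `n_iter` times with replacement (each
#' resample the size of the original voxel list), refits the Gaussian, and
#' marks an iteration PASS iff the fit is valid and every principal standard
#' deviation lies within the criteria. The p-value is the fraction of
#' failing iterations -- the estimated probability that the segment does not
#' satisfy the user's definition of a cell; invalid fits (non-positive-
#' definite, rank-deficient, or fewer than `min_voxels` positive voxels)
#' count as failures.
#'
#' Resampling is driven by a deterministic per-segment stream derived from
#' `(seed, segment$label)`, so results do not depend on processing order.
#'
#' @inheritParams fit_region_voxels
#' @param criteria a [cell_criteria()] (or a [detection_config()]).
#' @param n_iter number of bootstrap iterations (~1000).
#' @param seed integer root seed.
#' @param keep_samples keep the per-resample principal stds (for
#'   Figure-style diagnostics)?
#' @param min_voxels minimal positive-voxel count for a valid fit.
#' @return An object of class `bootstrap_result`: `p_value`,
#'   `n_iterations`, `mean_stds`/`sd_stds` (per principal axis, over valid
#'   resamples), `pass_mean_stds`, and -- when `keep_samples` --
#'   `per_resample_stds` (n_iter x 3, `NA` rows for invalid fits), `valid`
#'   and `pass` flags per iteration.
#' @export
bootstrap_segment <- function(raw, segment, radius, criteria,
                              n_iter = 1000L, seed = 1L,
                              keep_samples = TRUE, min_voxels = 10L) {
  criteria <- as_criteria(criteria)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) c3d_stop("c3d_error_config", "n_iter must be positive")
  region <- tryCatch(fit_region_voxels(raw, segment, radius),
                     c3d_error_empty_region = function(e) NULL)
  if (is.null(region)) {
    return(structure(list(p_value = 1, n_iterations = n_iter, n_done = n_iter,
                          n_fail = n_iter, n_valid = 0L, n_pass = 0L,
                          rejected = TRUE,
                          mean_stds = rep(NA_real_, 3),
                          sd_stds = rep(NA_real_, 3),
                          pass_mean_stds = rep(NA_real_, 3),
                          pass_sd_stds = rep(NA_real_, 3)),
                     class = "bootstrap_result"))
  }
  res <- .cpp_bootstrap(region$offsets, as.numeric(region$intensity), n_iter,
                        as.numeric(seed), as.integer(segment$label),
                        criteria$std_min, criteria$std_max,
                        criteria$amp_min, criteria$amp_max,
                        as.integer(min_voxels), -1L, isTRUE(keep_samples))
  structure(res, class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> p = %s (%d/%d failing resamples, %d valid fits)\n",
              format(x$p_value), x$n_fail, x$n_done, x$n_valid))
  if (x$n_valid > 0)
    cat(sprintf("  mean principal stds (valid fits): %.3g, %.3g, %.3g\n",
                x$mean_stds[1], x$mean_stds[2], x$mean_stds[3]))
  invisible(x)
}

#' Dump per-resample bootstrap diagnostics to CSV
#'
#' Writes one row per bootstrap iteration (iteration index, validity, pass
#' flag, fitted amplitude, and the three principal stds; `NA` for invalid
#' fits) for histogram-style inspection of a segment's fit distribution.
#'
#' @param result a [bootstrap_segment()] result obtained with
#'   `keep_samples = TRUE`.
#' @param path CSV file path.
#' @export
write_bootstrap_diagnostics <- function(result, path) {
  stopifnot(inherits(result, "bootstrap_result"))
  if (is.null(result$per_resample_stds))
    c3d_stop("c3d_error_config",
             "no per-resample record; rerun bootstrap_segment(keep_samples = TRUE)")
  df <- data.frame(iteration = seq_len(result$n_iterations),
                   valid = result$valid, pass = result$pass,
                   amplitude = result$per_resample_amplitude,
                   std1 = result$per_resample_stds[, 1],
                   std2 = result$per_resample_stds[, 2],
                   std3 = result$per_resample_stds[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Classify candidate segments into detected cells
#'
#' Runs [bootstrap_segment()] on every segment and emits one detection per
#' segment whose p-value falls below `config$p_threshold`. Segments whose
#' failure count already guarantees `p >= p_threshold` stop resampling early
#' (the emitted set and all reported p-values are identical to the full run).
#'
#' @param raw the unfiltered [volume()] the fits draw intensities from.
#' @param segments list of `segment3d` from [extract_segments()].
#' @param config a [detection_config()].
#' @param quiet suppress the progress message.
#' @return A `detections3d` data frame (see [detect_cells()] for columns).
#' @export
classify_segments <- function(raw, segments, config, quiet = TRUE) {
  raw <- as_volume(raw)
  stopifnot(inherits(config, "detection_config"))
  criteria <- as_criteria(config)
  n_iter <- config$bootstrap_iters
  fail_limit <- as.integer(ceiling(n_iter * config$p_threshold))

  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    region <- tryCatch(fit_region_voxels(raw, seg, config$fit_radius),
                       c3d_error_empty_region = function(e) NULL)
    if (is.null(region)) next
    res <- .cpp_bootstrap(region$offsets, as.numeric(region$intensity), n_iter,
                          as.numeric(config$rng_seed), as.integer(seg$label),
                          criteria$std_min, criteria$std_max,
                          criteria$amp_min, criteria$amp_max,
                          10L, fail_limit, FALSE)
    if (res$rejected || res$p_value >= config$p_threshold) next
    pk0 <- as.numeric(seg$peak) - 1  # 0-based voxel coordinates
    um <- pk0 * raw$spacing
    rows[[i]] <- data.frame(
      z = pk0[1], y = pk0[2], x = pk0[3],
      z_um = um[1], y_um = um[2], x_um = um[3],
      p_value = res$p_value,
      std1 = res$pass_mean_stds[1], std2 = res$pass_mean_stds[2],
      std3 = res$pass_mean_stds[3],
      peak_intensity = raw$data[seg$peak[1], seg$peak[2], seg$peak[3]],
      segment_voxels = seg$size, segment_label = seg$label)
  }
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(empty_detections())))
  out <- out[order(out$segment_label), , drop = FALSE]
  rownames(out) <- NULL
  c3d_log(quiet, "significance: %d of %d segments accepted as cells (p < %g)",
          nrow(out), length(segments), config$p_threshold)
  class(out) <- c("detections3d", "data.frame")
  out
}

empty_detections <- function() {
  data.frame(z = numeric(), y = numeric(), x = numeric(),
             z_um = numeric(), y_um = numeric(), x_um = numeric(),
             p_value = numeric(), std1 = numeric(), std2 = numeric(),
             std3 = numeric(), peak_intensity = numeric(),
             segment_voxels = integer(), segment_label = integer())
}
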