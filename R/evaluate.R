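# Evaluation against ground-truth centroids: one-to-one matching,
# precision / recall / F-score, and the decibel SNR measure.

as_centroids <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("z", "y", "x") %in% names(x)))
      c3d_stop("c3d_error_config", "centroid table needs z, y, x columns")
    x <- cbind(x$z, x$y, x$x)
  }
  x <- as.matrix(x)
  if (length(x) == 0L) x <- matrix(numeric(), 0L, 3L)
  if (ncol(x) != 3L)
    c3d_stop("c3d_error_config", "centroids must be an n x 3 (z, y, x) matrix")
  storage.mode(x) <- "double"
  x
}

#' Match detections to ground-truth centroids one-to-one
#'
#' Computes a maximum-cardinality one-to-one matching between detections and
#' truth points among all pairs with Euclidean distance at most `tolerance`
#' (augmenting-path bipartite matching; candidate partners are tried in
#' order of ascending distance, then index, so the result is deterministic).
#'
#' @param detections detected centroids: a `detections3d` data frame or an
#'   n x 3 (z, y, x) matrix (voxel units).
#' @param truth ground-truth centroids, same format.
#' @param tolerance maximal matching distance in voxels.
#' @return An object of class `match_result`: counts `tp`, `fp`, `fn`, the
#'   matched `pairs` (data frame of detection/truth indices and distances)
#'   and `tolerance`.
#' @export
match_detections <- function(detections, truth, tolerance) {
  det <- as_centroids(detections)
  tru <- as_centroids(truth)
  if (!is.numeric(tolerance) || tolerance <= 0)
    c3d_stop("c3d_error_config", "tolerance must be positive")
  nd <- nrow(det); nt <- nrow(tru)

  adj <- vector("list", nd)
  if (nd > 0 && nt > 0) {
    d2 <- outer(det[, 1], tru[, 1], "-")^2 +
      outer(det[, 2], tru[, 2], "-")^2 +
      outer(det[, 3], tru[, 3], "-")^2
    tol2 <- tolerance^2
    for (i in seq_len(nd)) {
      cand <- which(d2[i, ] <= tol2)
      adj[[i]] <- cand[order(d2[i, cand], cand)]
    }
  }

  match_t <- integer(nt)  # truth -> detection (0 = unmatched)
  match_d <- integer(nd)
  for (i in seq_len(nd)) {
    seen <- logical(nt)
    augment <- function(d) {
      for (t in adj[[d]]) {
        if (!seen[t]) {
          seen[t] <<- TRUE
          if (match_t[t] == 0L || augment(match_t[t])) {
            match_t[t] <<- d
            match_d[d] <<- t
            return(TRUE)
          }
        }
      }
      FALSE
    }
    augment(i)
  }

  matched <- which(match_d > 0L)
  pairs <- data.frame(detection = matched, truth = match_d[matched])
  pairs$distance <- if (nrow(pairs)) sqrt(rowSums((det[pairs$detection, , drop = FALSE] -
                                                   tru[pairs$truth, , drop = FALSE])^2))
                    else numeric()
  structure(list(tp = nrow(pairs), fp = nd - nrow(pairs), fn = nt - nrow(pairs),
                 pairs = pairs, tolerance = tolerance),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tp = %d, fp = %d, fn = %d (tolerance %g voxels)\n",
              x$tp, x$fp, x$fn, x$tolerance))
  invisible(x)
}

#' Precision, recall and F-score of a match
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F = 2 * precision * recall / (precision + recall)`; a zero denominator
#' yields 0 by convention.
#'
#' @param match a [match_detections()] result (or a list with `tp`, `fp`,
#'   `fn`).
#' @return A list with `precision`, `recall` and `f`.
#' @export
f_score <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f = f)
}

#' Decibel signal-to-noise ratio of a volume
#'
#' `SNR = 20 * log10(signal_amplitude / noise_amplitude)` where the signal
#' amplitude is the mean, over the given cell peaks, of the difference
#' between the raw peak intensity and the local background, and the noise
#' amplitude is the standard deviation of the volume after high-pass
#' filtering (see [highpass_filter()]). The local background of a peak is
#' estimated as the mean raw intensity in a spherical shell between
#' `radius` and `2 * radius` around it; the shell mean is unbiased by voxel
#' noise, so the measure stays meaningful at strongly negative SNR (a
#' low-quantile estimator would saturate once noise dominates).
#'
#' @param vol the raw [volume()].
#' @param peaks cell peak centroids, 0-based (z, y, x) voxel coordinates
#'   (matrix or data frame); at least one.
#' @param sigma_high standard deviation (voxels) of the high-pass Gaussian
#'   defining the noise measure; use the value from the matching
#'   [detection_config()].
#' @param radius inner shell radius in voxels (default 7, the fit radius).
#' @return An object of class `snr_report`: `signal_amplitude`,
#'   `noise_amplitude`, `snr_db`.
#' @export
compute_snr <- function(vol, peaks, sigma_high, radius = 7) {
  vol <- as_volume(vol)
  pk <- as_centroids(peaks)
  if (nrow(pk) < 1L) c3d_stop("c3d_error_config", "need at least one peak")

  noise <- sd(highpass_filter(vol, sigma_high)$data)
  if (noise == 0)
    c3d_stop("c3d_error_degenerate", "noise amplitude is zero (noise-free input)")

  amps <- peak_amplitudes(vol$data, pk, radius)
  signal <- mean(amps)
  structure(list(signal_amplitude = signal, noise_amplitude = noise,
                 snr_db = 20 * log10(signal / noise)),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> %.2f dB (signal %.4g / noise %.4g)\n",
              x$snr_db, x$signal_amplitude, x$noise_amplitude))
  invisible(x)
}

# integer offsets of the shell radius < |d| <= 2*radius (list of 3 columns)
shell_offsets <- function(radius) {
  r2 <- ceiling(2 * radius)
  g <- seq(-r2, r2)
  off <- as.matrix(expand.grid(dz = g, dy = g, dx = g))
  d2 <- rowSums(off^2)
  off[d2 > radius^2 & d2 <= (2 * radius)^2, , drop = FALSE]
}

# signal amplitude per peak: raw value at the (rounded) peak voxel minus the
# mean of the shell intensities around it
peak_amplitudes <- function(data, pk, radius) {
  d <- dim(data)
  off <- shell_offsets(radius)
  vapply(seq_len(nrow(pk)), function(i) {
    p <- pmin(pmax(round(pk[i, ]) + 1, 1), d)  # 1-based, clamped
    sh <- sweep(off, 2, p, "+")
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    bg <- mean(data[sh[ok, , drop = FALSE]])
    data[p[1], p[2], p[3]] - bg
  }, numeric(1))
}
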