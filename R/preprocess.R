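# Preprocessing: histogram matching, autofluorescence subtraction,
# FFT band-pass filtering and thresholding.

#' Intensity histogram of a volume
#'
#' Bins span the full intensity range of the data. A constant volume yields
#' a single occupied unit-width bin centered on the constant.
#'
#' @param vol a [volume()] or 3D array.
#' @param n_bins number of bins (default 1024).
#' @return An object of class `intensity_histogram` with fields `bin_edges`
#'   (length `n_bins + 1`), `counts` and `cumulative` (normalized CDF).
#' @export
histogram_of <- function(vol, n_bins = 1024L) {
  vol <- as_volume(vol)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    c3d_stop("c3d_error_config", "n_bins must be a positive integer")
  x <- vol$data
  lo <- min(x); hi <- max(x)
  if (lo == hi) {
    edges <- c(lo - 0.5, lo + 0.5)
    counts <- length(x)
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(bin, nbins = n_bins)
  }
  structure(list(bin_edges = edges, counts = as.numeric(counts),
                 cumulative = cumsum(counts) / sum(counts)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d bins over [%g, %g], %g voxels\n",
              length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], sum(x$counts)))
  invisible(x)
}

#' Write / read a reference histogram
#'
#' Persists a histogram as a 2-column CSV (`bin_edge`, `count`; the final
#' edge row carries count 0) so that one reference -- taken from the sample
#' on which parameters were tuned -- can normalize a whole batch.
#'
#' @param hist an [histogram_of()] result.
#' @param path CSV file path.
#' @export
write_reference_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "intensity_histogram"))
  df <- data.frame(bin_edge = hist$bin_edges, count = c(hist$counts, 0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_histogram
#' @export
read_reference_histogram <- function(path) {
  if (!file.exists(path))
    c3d_stop("c3d_error_unreadable", "histogram file '%s' does not exist", path)
  df <- read.csv(path)
  if (!all(c("bin_edge", "count") %in% names(df)))
    c3d_stop("c3d_error_unreadable", "'%s' is not a (bin_edge, count) histogram CSV", path)
  counts <- df$count[-nrow(df)]
  structure(list(bin_edges = df$bin_edge, counts = as.numeric(counts),
                 cumulative = cumsum(counts) / sum(counts)),
            class = "intensity_histogram")
}

#' Match a volume's intensity distribution to a reference histogram
#'
#' Classical quantile (CDF-inverse) mapping: each voxel is mapped to the
#' reference quantile of its mid-rank, so the output's empirical CDF matches
#' the reference CDF to within one bin width while voxel rank order is
#' preserved (ties stay tied). This makes one parameter set transferable
#' across samples whose staining or acquisition gain differ.
#'
#' @param vol a [volume()].
#' @param reference an `intensity_histogram` (from [histogram_of()] or
#'   [read_reference_histogram()]).
#' @return A volume with remapped intensities.
#' @export
match_histogram <- function(vol, reference) {
  vol <- as_volume(vol)
  stopifnot(inherits(reference, "intensity_histogram"))
  x <- vol$data
  n <- length(x)
  # mid-rank empirical CDF value of each voxel (constant volume -> 0.5)
  u <- (rank(x, ties.method = "average") - 0.5) / n
  # reference quantile function: interpolate edges against the CDF
  cdf <- c(0, reference$cumulative)
  y <- approx(x = cdf, y = reference$bin_edges, xout = u,
              rule = 2, ties = "ordered")$y
  vol_with(vol, array(y, dim = dim(x)))
}

#' Subtract a co-registered autofluorescence channel
#'
#' Structures such as blood vessels fluoresce across wavelengths, while a
#' specific marker emits only in its own channel; an image taken at a second
#' wavelength therefore captures the autofluorescent background alone. The
#' background channel is first histogram-matched to the signal channel (the
#' two channels' gains differ), then subtracted voxel-wise; negative
#' differences are clipped to zero.
#'
#' A constant background channel (e.g. all zeros) carries no distribution to
#' match and is subtracted verbatim.
#'
#' @param signal the marker channel, a [volume()].
#' @param autofluor the background channel, same shape.
#' @return A non-negative volume: `signal - matched(autofluor)`.
#' @export
subtract_background_channel <- function(signal, autofluor) {
  signal <- as_volume(signal); autofluor <- as_volume(autofluor)
  if (!identical(dim(signal$data), dim(autofluor$data)))
    c3d_stop("c3d_error_shape_mismatch",
             "signal and autofluorescence volumes have different shapes")
  matched <- if (min(autofluor$data) == max(autofluor$data)) autofluor
             else match_histogram(autofluor, histogram_of(signal))
  vol_with(signal, pmax(signal$data - matched$data, 0))
}

# ---- FFT Gaussian filtering -------------------------------------------------

# 1D frequency response of a sampled, sum-normalized Gaussian kernel of
# standard deviation s (voxels) on a circle of length n. Normalization makes
# the DC gain exactly 1, so the band-pass difference annihilates constants.
gauss_transfer_1d <- function(n, s) {
  half <- n %/% 2
  offs <- ((seq_len(n) - 1 + half) %% n) - half
  w <- exp(-offs^2 / (2 * s^2))
  Re(stats::fft(w / sum(w)))
}

# Filter a 3D array with a separable-Gaussian-based transfer function.
# Volumes are padded by `pad` voxels of edge replication (periodic FFT
# boundaries otherwise wrap opposite faces into each other), filtered in the
# frequency domain, and cropped back.
fft_gauss_filter <- function(x, sigma_low = NULL, sigma_high = NULL,
                             mode = c("bandpass", "highpass", "lowpass")) {
  mode <- match.arg(mode)
  d <- dim(x)
  smax <- pmax(if (is.null(sigma_low)) 0 else sigma_low,
               if (is.null(sigma_high)) 0 else sigma_high)
  pad <- pmin(ceiling(3 * smax), d)  # no point padding beyond one replica
  np <- vapply(d + 2L * pad, next_fast_size, integer(1))

  idx <- lapply(1:3, function(a)
    pmin(pmax(seq_len(np[a]) - pad[a], 1L), d[a]))
  P <- x[idx[[1]], idx[[2]], idx[[3]]]

  transfer3 <- function(s) {
    fz <- gauss_transfer_1d(np[1], s[1])
    fy <- gauss_transfer_1d(np[2], s[2])
    fx <- gauss_transfer_1d(np[3], s[3])
    outer(outer(fz, fy), fx)
  }
  H <- switch(mode,
    bandpass = transfer3(sigma_low) - transfer3(sigma_high),
    highpass = 1 - transfer3(sigma_high),
    lowpass = transfer3(sigma_low))

  out <- Re(stats::fft(stats::fft(P) * H, inverse = TRUE)) / prod(np)
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])]
}

#' Band-pass filter a volume (difference of Gaussians)
#'
#' Convolves the volume with `Gaussian(sigma_low) - Gaussian(sigma_high)`,
#' computed in the frequency domain in a single FFT pass. The low-pass part
#' (sigma below the cell radius) erases intra-nucleus staining patchiness and
#' voxel noise; the high-pass part (sigma 1.5-2x above the cell radius)
#' removes smooth background so that one global threshold separates cells
#' everywhere. Both kernels are sampled, sum-normalized Gaussians, so the
#' filter output has exactly zero mean gain (a constant volume maps to ~0).
#' The output may be negative; thresholding handles that downstream.
#'
#' @param vol a [volume()].
#' @param sigma_low,sigma_high Gaussian standard deviations in voxels, scalar
#'   or per-axis (z, y, x); `0 < sigma_low < sigma_high` per axis.
#' @return A volume of band-passed intensities.
#' @export
bandpass_filter <- function(vol, sigma_low, sigma_high) {
  vol <- as_volume(vol)
  sl <- as_triple(sigma_low, "sigma_low")
  sh <- as_triple(sigma_high, "sigma_high")
  if (any(sl <= 0) || any(sl >= sh))
    c3d_stop("c3d_error_config", "need 0 < sigma_low < sigma_high on every axis")
  vol_with(vol, fft_gauss_filter(vol$data, sl, sh, mode = "bandpass"))
}

#' High-pass filter a volume
#'
#' Subtracts the Gaussian(sigma_high)-smoothed volume from the volume itself
#' (transfer `1 - G`). This is the filter in whose output the noise amplitude
#' of the dB SNR measure is defined (see [compute_snr()]).
#'
#' @inheritParams bandpass_filter
#' @export
highpass_filter <- function(vol, sigma_high) {
  vol <- as_volume(vol)
  sh <- as_triple(sigma_high, "sigma_high")
  if (any(sh <= 0)) c3d_stop("c3d_error_config", "sigma_high must be positive")
  vol_with(vol, fft_gauss_filter(vol$data, sigma_high = sh, mode = "highpass"))
}

#' Zero all voxels below a fraction of the maximal intensity
#'
#' Voxels with intensity below `fraction * max(vol)` are set to zero;
#' negative intensities (as produced by the band-pass filter) are always
#' zeroed. The threshold is relative to the maximum of the volume being
#' thresholded, i.e. of the band-passed volume in the detection pipeline.
#'
#' @param vol a [volume()].
#' @param fraction threshold as a fraction of the maximal intensity, in
#'   \[0, 1\]; typically 0.05-0.10.
#' @return The thresholded volume (non-negative).
#' @export
apply_threshold <- function(vol, fraction) {
  vol <- as_volume(vol)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction < 0 || fraction > 1)
    c3d_stop("c3d_error_config", "'fraction' must be a single number in [0, 1]")
  x <- vol$data
  thr <- fraction * max(x)
  x[x < thr | x < 0] <- 0
  vol_with(vol, x)
}
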