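# Watershed segmentation of the thresholded band-passed volume into
# candidate one-cell segments.

#' Watershed segmentation on the negated image
#'
#' Partitions the positive support of a (band-passed, thresholded) volume
#' into disjoint segments, each containing exactly one regional intensity
#' maximum: flooding the negated image, every maximum seeds a basin, voxels
#' are visited in order of decreasing intensity, and voxels where two basins
#' meet become watershed lines and keep label 0. Zero-intensity voxels are
#' background and are never flooded (they do not form a catchment basin of
#' their own). 6-connectivity; a flat maximum (plateau) forms a single
#' marker; all tie-breaks are deterministic (lexicographic (z, y, x) scan
#' order, FIFO among equal intensities).
#'
#' @param filtered a non-negative [volume()], typically
#'   `apply_threshold(bandpass_filter(...))`.
#' @return An integer array of class `label_map`, same shape as the input:
#'   0 marks background and watershed lines, labels `1..K` the segments.
#'   `K` equals the number of regional maxima of the positive support.
#' @export
watershed_segments <- function(filtered) {
  filtered <- as_volume(filtered)
  d <- dim(filtered$data)
  labels <- .cpp_watershed(as.numeric(filtered$data), as.integer(d))
  n <- attr(labels, "n_labels")
  dim(labels) <- d
  structure(labels, n_labels = n, class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_map> %d x %d x %d voxels, %d segments\n",
              d[1], d[2], d[3], n_segments(x)))
  invisible(x)
}

#' Number of segments in a label map
#' @param labels a `label_map`.
#' @export
n_segments <- function(labels) {
  n <- attr(labels, "n_labels")
  if (is.null(n)) n <- max(0L, max(labels))
  as.integer(n)
}

#' Remove segments smaller than the expected cell volume
#'
#' Segments with fewer than `min_size` voxels are relabeled to 0 and the
#' surviving labels are compacted to `1..K'`, preserving their relative
#' order. Voxel membership of surviving segments is unchanged.
#'
#' @param labels a `label_map` from [watershed_segments()].
#' @param min_size minimal segment size in voxels (typically 10-100).
#' @export
remove_small_segments <- function(labels, min_size) {
  stopifnot(inherits(labels, "label_map"))
  min_size <- as.integer(min_size)
  k <- n_segments(labels)
  if (k == 0L) return(labels)
  sizes <- tabulate(labels[labels > 0L], nbins = k)
  keep <- sizes >= max(min_size, 1L)
  map <- c(0L, ifelse(keep, cumsum(keep), 0L))
  out <- map[as.integer(labels) + 1L]
  dim(out) <- dim(labels)
  structure(out, n_labels = sum(keep), class = "label_map")
}

#' Extract per-segment summaries from a label map
#'
#' @param labels a `label_map`.
#' @param filtered the volume the labels were computed from (used to locate
#'   each segment's intensity peak; ties broken toward the lexicographically
#'   smallest (z, y, x) coordinate).
#' @return A list of `segment3d` objects with fields `label`, `peak`
#'   (1-based (z, y, x) array index of the segment's intensity maximum),
#'   `size`, `voxels` (n x 3 matrix of 1-based (z, y, x) member coordinates)
#'   and `lin` (linear indices into the array).
#' @export
extract_segments <- function(labels, filtered) {
  stopifnot(inherits(labels, "label_map"))
  filtered <- as_volume(filtered)
  if (!identical(dim(labels), dim(filtered$data)))
    c3d_stop("c3d_error_shape_mismatch", "label map and volume shapes differ")
  k <- n_segments(labels)
  if (k == 0L) return(list())

  pos <- which(labels > 0L)
  lab <- as.integer(labels[pos])
  val <- filtered$data[pos]
  coord <- arrayInd(pos, dim(labels))  # columns are (z, y, x)
  ord <- order(lab, -val, coord[, 1], coord[, 2], coord[, 3], method = "radix")
  peak_rows <- ord[!duplicated(lab[ord])]  # first row per label = its peak
  sizes <- tabulate(lab, nbins = k)
  groups <- split(seq_along(pos), lab)

  lapply(seq_len(k), function(l) {
    rows <- groups[[as.character(l)]]
    structure(list(label = l,
                   peak = coord[peak_rows[l], ],
                   size = sizes[l],
                   voxels = coord[rows, , drop = FALSE],
                   lin = pos[rows]),
              class = "segment3d")
  })
}

#' @export
print.segment3d <- function(x, ...) {
  cat(sprintf("<segment3d> label %d, %d voxels, peak at (z,y,x) = (%d, %d, %d)\n",
              x$label, x$size, x$peak[1] - 1L, x$peak[2] - 1L, x$peak[3] - 1L))
  invisible(x)
}

#' Write a label map as a 16-bit multi-page TIFF (debug aid)
#'
#' @param labels a `label_map` with at most 65535 segments.
#' @param path output path.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  if (n_segments(labels) > 65535L)
    c3d_stop("c3d_error_unwritable", "more than 65535 segments; cannot store as 16-bit TIFF")
  write_volume(volume(array(as.numeric(labels), dim(labels))), path, bits = 16L)
}
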