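# Volume container and TIFF I/O
#
# A volume is a 3D intensity grid stored as a base array with dim (nz, ny, nx)
# -- axis order (z, y, x), matching the page/row/column storage order of a
# TIFF stack -- plus a physical voxel spacing in micrometers per axis and a
# free-text sample label. All user-facing voxel coordinates (detections,
# ground-truth tables, evaluation) are 0-based (z, y, x).

#' Create a 3D intensity volume
#'
#' Wraps a 3D numeric array together with its per-axis physical voxel spacing
#' and a sample label. Axis order is (z, y, x): `data[z, y, x]` is the voxel
#' in slice `z`, row `y`, column `x`.
#'
#' Raw microscopy volumes are non-negative; intermediate band-pass-filtered
#' volumes may contain negative values, so negativity is not rejected here.
#'
#' @param data 3D numeric array, axis order (z, y, x); all values finite.
#' @param spacing physical voxel size in micrometers per axis, a scalar or a
#'   length-3 (z, y, x) vector of strictly positive values. Default 1.
#' @param label free-text sample identifier.
#' @return An object of class `volume3d`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), label = "") {
  if (is.matrix(data)) dim(data) <- c(1L, dim(data))
  if (!is.array(data) || length(dim(data)) != 3L)
    c3d_stop("c3d_error_volume", "'data' must be a 3D array (z, y, x)")
  storage.mode(data) <- "double"
  if (anyNA(data) || !all(is.finite(data)))
    c3d_stop("c3d_error_volume", "volume intensities must all be finite")
  spacing <- as_triple(spacing, "spacing")
  if (any(spacing <= 0))
    c3d_stop("c3d_error_volume", "voxel spacing must be strictly positive")
  structure(list(data = data, spacing = spacing, label = as.character(label)[1]),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (um): %g, %g, %g\n", x$spacing[1], x$spacing[2], x$spacing[3]))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  cat(sprintf("  intensity range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

as_volume <- function(x, template = NULL) {
  if (inherits(x, "volume3d")) return(x)
  if (is.null(template)) volume(x)
  else volume(x, spacing = template$spacing, label = template$label)
}

# replace the data of a volume, keeping spacing/label (no revalidation cost)
vol_with <- function(vol, data) {
  vol$data <- data
  vol
}

read_page <- function(page, path) {
  if (is.list(page)) page <- page[[1]]
  d <- dim(page)
  if (length(d) == 3L) {
    if (d[3] == 1L) page <- page[, , 1L]
    else c3d_stop("c3d_error_unreadable",
                  "'%s' has %d channels; only single-channel (grayscale) TIFFs are supported",
                  path, d[3])
  }
  page
}

#' Read a 3D volume from TIFF
#'
#' Reads either a multi-page TIFF stack (slices ordered by page index) or a
#' directory of single-slice TIFF files (slices ordered by lexicographically
#' sorted filename). 8/16-bit integer data are read losslessly as integers;
#' 32-bit float TIFFs are read as-is.
#'
#' @param path a TIFF file or a directory of 2D TIFF slices.
#' @param dialect `"auto"` (directory implies `"slices"`), `"stack"` or
#'   `"slices"`.
#' @inheritParams volume
#' @return A [volume()] of shape (n_slices, height, width).
#' @export
read_volume <- function(path, dialect = c("auto", "stack", "slices"),
                        spacing = c(1, 1, 1), label = basename(path)) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- if (dir.exists(path)) "slices" else "stack"

  if (dialect == "stack") {
    if (!file.exists(path))
      c3d_stop("c3d_error_unreadable", "cannot read volume: '%s' does not exist", path)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                        c3d_stop("c3d_error_unreadable", "cannot decode TIFF '%s': %s",
                                 path, conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, read_page, path = path)
  } else {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L)
      c3d_stop("c3d_error_empty", "no TIFF slices found in directory '%s'", path)
    pages <- lapply(files, function(f) {
      p <- tryCatch(tiff::readTIFF(f, as.is = TRUE),
                    error = function(e)
                      c3d_stop("c3d_error_unreadable", "cannot decode TIFF '%s': %s",
                               f, conditionMessage(e)))
      read_page(p, f)
    })
  }

  if (length(pages) == 0L)
    c3d_stop("c3d_error_empty", "'%s' contains zero slices", path)
  shapes <- vapply(pages, function(p) dim(p), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    c3d_stop("c3d_error_slice_shape",
             "slices of '%s' have inconsistent shapes (first is %dx%d)",
             path, shapes[1, 1], shapes[2, 1])

  arr <- array(0, dim = c(length(pages), shapes[1, 1], shapes[2, 1]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  volume(arr, spacing = spacing, label = label)
}

#' Write a volume as a multi-page integer TIFF
#'
#' Writes 8- or 16-bit grayscale pages. Data must be integer-valued and fit
#' the chosen bit depth (the round trip through [read_volume()] is then
#' bit-identical); rescale or round beforehand for float data.
#'
#' @param vol a [volume()].
#' @param path output file path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, bits = 16L) {
  vol <- as_volume(vol)
  if (!bits %in% c(8L, 16L))
    c3d_stop("c3d_error_unwritable", "only 8- and 16-bit TIFF output is supported")
  mx <- 2^bits - 1
  d <- vol$data
  if (any(d < 0) || any(d > mx) || any(d != round(d)))
    c3d_stop("c3d_error_unwritable",
             "data must be integer-valued in [0, %d] for %d-bit TIFF output", mx, bits)
  pages <- lapply(seq_len(dim(d)[1]), function(z) d[z, , ] / mx)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits)),
                 error = function(e)
                   c3d_stop("c3d_error_unwritable", "cannot write TIFF '%s': %s",
                            path, conditionMessage(e)))
  invisible(path)
}
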