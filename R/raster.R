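#' Grayscale raster image with physical pixel size
#'
#' Container for stained-cell and proximity-ligation images. The grid is
#' row-major with row 1 at the top of the image; `long_axis` records which
#' matrix axis runs along the cell's long axis (striation ROIs are taken with
#' their long side on that axis).
#'
#' @param data Numeric matrix of grayscale intensities (rows = image rows).
#' @param pixel_size_um Physical size of one pixel in micrometres.
#' @param long_axis `"columns"` (default) if the cell's long axis runs along
#'   matrix columns (left-right in the image), `"rows"` otherwise.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(data, pixel_size_um, long_axis = c("columns", "rows")) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("'data' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(data) < 1L || ncol(data) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  long_axis <- match.arg(long_axis)
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 long_axis = long_axis),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px (%.3g x %.3g um), %.3g um/px, long axis: %s\n",
              nrow(x$data), ncol(x$data),
              nrow(x$data) * x$pixel_size_um, ncol(x$data) * x$pixel_size_um,
              x$pixel_size_um, x$long_axis))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$data)

#' Binary foreground mask
#'
#' @param data Logical matrix, `TRUE` on the stained (foreground) phase.
#' @param pixel_size_um Pixel size in micrometres.
#' @param threshold_used Threshold that produced the mask (NA for masks not
#'   derived by thresholding).
#' @param long_axis Orientation flag inherited from the source image.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, pixel_size_um, threshold_used = NA_real_,
                        long_axis = c("columns", "rows")) {
  if (!is.matrix(data) || !is.logical(data)) {
    stop("'data' must be a logical matrix", call. = FALSE)
  }
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  long_axis <- match.arg(long_axis)
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 threshold_used = threshold_used, long_axis = long_axis),
            class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$data)

#' Extract a rectangular region of interest
#'
#' Cuts a sub-image of physical size `size_um` whose top-left corner sits at
#' `origin_um`, both in micrometres measured from the image's top-left corner
#' (x rightward along columns, y downward along rows). An ROI that does not
#' fit entirely inside the image is an error; there is no silent clipping.
#' The conventional striation ROI is 5 x 40 um with the 40 um side along the
#' cell's long axis.
#'
#' @param image A [raster_image()].
#' @param origin_um Numeric length-2, `c(x, y)` of the ROI top-left corner in
#'   micrometres.
#' @param size_um Numeric length-2, `c(width, height)` in micrometres
#'   (width along x/columns, height along y/rows).
#' @return A [raster_image()] of dimension `round(size_um / pixel_size_um)`.
#' @export
select_roi <- function(image, origin_um = c(0, 0), size_um) {
  stopifnot(inherits(image, "raster_image"))
  if (length(origin_um) != 2L || length(size_um) != 2L) {
    stop("'origin_um' and 'size_um' must have length 2 (x, y)", call. = FALSE)
  }
  if (any(size_um <= 0)) stop("ROI size must be positive", call. = FALSE)
  px <- image$pixel_size_um
  col0 <- round(origin_um[1] / px)   # 0-based pixel offsets
  row0 <- round(origin_um[2] / px)
  ncol_roi <- round(size_um[1] / px)
  nrow_roi <- round(size_um[2] / px)
  if (col0 < 0 || row0 < 0 ||
      col0 + ncol_roi > ncol(image$data) ||
      row0 + nrow_roi > nrow(image$data)) {
    stop(sprintf(
      "ROI [%g,%g] + %g x %g um exceeds image bounds (%g x %g um)",
      origin_um[1], origin_um[2], size_um[1], size_um[2],
      ncol(image$data) * px, nrow(image$data) * px), call. = FALSE)
  }
  sub <- image$data[(row0 + 1L):(row0 + nrow_roi),
                    (col0 + 1L):(col0 + ncol_roi), drop = FALSE]
  raster_image(sub, px, image$long_axis)
}

#' Binarize a grayscale image
#'
#' Thresholds an image into stained foreground versus background. The default
#' method is Otsu's threshold (minimizer of intra-class variance) computed on
#' the image itself; a fixed threshold can be supplied instead. Foreground is
#' the bright (stained) phase; use `invert = TRUE` when the stain is rendered
#' dark on a light background.
#'
#' @param image A [raster_image()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold value, required for `method = "fixed"`.
#' @param invert If `TRUE`, foreground is the phase *below* the threshold.
#' @return A [binary_mask()] carrying the threshold used.
#' @export
binarize <- function(image, method = c("otsu", "fixed"),
                     fixed_threshold = NULL, invert = FALSE) {
  stopifnot(inherits(image, "raster_image"))
  method <- match.arg(method)
  th <- if (method == "otsu") {
    otsu_threshold(as.vector(image$data))
  } else {
    if (is.null(fixed_threshold) || !is.finite(fixed_threshold)) {
      stop("method = \"fixed\" requires a finite 'fixed_threshold'",
           call. = FALSE)
    }
    fixed_threshold
  }
  fg <- if (invert) image$data < th else image$data > th
  binary_mask(fg, image$pixel_size_um, threshold_used = th,
              long_axis = image$long_axis)
}

#' Read / write grayscale TIFF images
#'
#' Thin wrappers over the tiff package that attach the physical pixel size.
#' Images are stored with intensities rescaled to `[0, 1]` (16-bit on disk)
#' and restored to the original grayscale range on read via the `range`
#' argument.
#'
#' @param path File path.
#' @param image A [raster_image()] (for writing).
#' @param pixel_size_um Pixel size to attach on read.
#' @param range Length-2 grayscale range the `[0, 1]` TIFF values map to.
#' @param long_axis Orientation flag to attach on read.
#' @return `read_raster_tiff` returns a [raster_image()]; `write_raster_tiff`
#'   returns the path invisibly.
#' @export
read_raster_tiff <- function(path, pixel_size_um, range = c(0, 255),
                             long_axis = c("columns", "rows")) {
  long_axis <- match.arg(long_axis)
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]   # take first channel if multi
  raster_image(range[1] + m * (range[2] - range[1]), pixel_size_um, long_axis)
}

#' @rdname read_raster_tiff
#' @export
write_raster_tiff <- function(image, path, range = c(0, 255)) {
  stopifnot(inherits(image, "raster_image"))
  m <- (image$data - range[1]) / (range[2] - range[1])
  m[m < 0] <- 0; m[m > 1] <- 1
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}
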