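#' Proximity-ligation staining density
#'
#' Staining density of a PLA image is the area covered by signal normalized
#' to the area of the cell: thresholded foreground pixels inside the cell
#' mask divided by the mask pixel count. Thresholding is restricted to the
#' intensities inside the mask (per-image Otsu by default), so background
#' outside the cell never influences the threshold.
#'
#' @param image A [raster_image()].
#' @param cell_mask A [binary_mask()] of the cell area, congruent with the
#'   image.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold for `method = "fixed"`.
#' @return A list of class `pla_result`: `signal_area_um2`, `cell_area_um2`,
#'   `density` in `[0, 1]`, and `threshold_used`.
#' @export
pla_density <- function(image, cell_mask, method = c("otsu", "fixed"),
                        fixed_threshold = NULL) {
  stopifnot(inherits(image, "raster_image"),
            inherits(cell_mask, "binary_mask"))
  if (!identical(dim(image$data), dim(cell_mask$data))) {
    stop("image and cell mask must have identical dimensions", call. = FALSE)
  }
  if (!any(cell_mask$data)) stop("empty cell mask", call. = FALSE)
  method <- match.arg(method)
  vals <- image$data[cell_mask$data]
  th <- if (method == "otsu") {
    otsu_threshold(vals)
  } else {
    if (is.null(fixed_threshold) || !is.finite(fixed_threshold)) {
      stop("method = \"fixed\" requires a finite 'fixed_threshold'",
           call. = FALSE)
    }
    fixed_threshold
  }
  signal_px <- sum(vals > th)
  cell_px <- length(vals)
  px_area <- image$pixel_size_um^2
  structure(list(signal_area_um2 = signal_px * px_area,
                 cell_area_um2 = cell_px * px_area,
                 density = signal_px / cell_px,
                 threshold_used = th),
            class = "pla_result")
}
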