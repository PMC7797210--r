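#' Staining density of a binary mask
#'
#' Fraction of pixels on the stained phase of a binarized image: foreground
#' pixel count divided by total pixel count.
#'
#' @param mask A [binary_mask()].
#' @return Density in `[0, 1]`.
#' @export
staining_density <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (length(mask$data) == 0L) stop("empty mask", call. = FALSE)
  mean(mask$data)
}

#' Longitudinal waveform of a binarized striation ROI
#'
#' Collapses a binarized ROI to a one-dimensional waveform along the cell's
#' long axis: one value per long-axis position, equal to the mean of the mask
#' across the short axis. Averaging the full short axis (rather than sampling
#' a single pixel line) smooths over local stripe interruptions; the profile
#' mean equals the mask's staining density exactly.
#'
#' @param mask A [binary_mask()] from a long-axis-aligned ROI.
#' @return Numeric vector, one value in `[0, 1]` per long-axis pixel.
#' @export
longitudinal_profile <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (length(mask$data) == 0L) stop("empty mask", call. = FALSE)
  if (mask$long_axis == "columns") colMeans(mask$data) else rowMeans(mask$data)
}

#' Spatial power spectrum and power of regularity
#'
#' Converts a longitudinal staining waveform into a one-sided spatial power
#' spectrum by FFT and measures the "power of regularity": the maximum
#' spectral power in a band around the sarcomeric spatial frequency
#' (default 0.5 cycles/um, the reciprocal of the ~2 um T-tubule spacing).
#'
#' The profile mean (DC) is removed before the transform and no window is
#' applied by default (a Hann window is available via `window = "hann"`).
#' Power is normalized as `|X_k|^2 / n^2` and folded to one side, so the sum
#' of the one-sided power equals the population variance of the profile
#' (Parseval's identity), making total power directly comparable to the
#' waveform's amplitude structure.
#'
#' @param profile Numeric waveform (one sample per long-axis pixel).
#' @param pixel_size_um Spatial sampling interval in micrometres.
#' @param f0 Target spatial frequency in cycles/um (default 0.5).
#' @param band_halfwidth Half-width of the search band around `f0` in
#'   cycles/um (default 0.1, accommodating period jitter around "~2 um").
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return A list of class `striation_spectrum` with `frequencies`
#'   (cycles/um, ascending from 0), `power`, `regularity_power` (band
#'   maximum), `f_peak` (frequency of the global non-DC maximum), `f0`, and
#'   `band_halfwidth`.
#' @export
regularity_power <- function(profile, pixel_size_um, f0 = 0.5,
                             band_halfwidth = 0.1,
                             window = c("rectangular", "hann")) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(f0, "f0")
  window <- match.arg(window)
  n <- length(profile)
  if (n * pixel_size_um < 1 / f0) {
    stop(sprintf(
      "profile (%.3g um) is shorter than one period at f0 = %g cycles/um",
      n * pixel_size_um, f0), call. = FALSE)
  }
  x <- profile - mean(profile)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    x <- x * w
  }
  X <- stats::fft(x)
  full_power <- Mod(X)^2 / n^2
  # fold to one-sided spectrum; double interior bins so sum equals variance
  n_half <- floor(n / 2) + 1L
  power <- full_power[seq_len(n_half)]
  interior <- 2:(n_half - 1L)
  if (n %% 2 == 0) {
    power[interior] <- 2 * power[interior]       # Nyquist bin unpaired
  } else if (n_half >= 2L) {
    power[2:n_half] <- 2 * power[2:n_half]
  }
  freqs <- (seq_len(n_half) - 1L) / (n * pixel_size_um)
  band <- which(freqs >= f0 - band_halfwidth & freqs <= f0 + band_halfwidth &
                  freqs > 0)
  reg_power <- if (length(band)) max(power[band]) else 0
  non_dc <- which(freqs > 0)
  f_peak <- if (length(non_dc)) freqs[non_dc][which.max(power[non_dc])] else NA_real_
  structure(list(frequencies = freqs, power = power,
                 regularity_power = reg_power, f_peak = f_peak,
                 f0 = f0, band_halfwidth = band_halfwidth, window = window),
            class = "striation_spectrum")
}

#' One-call striation metrics for an image
#'
#' Runs the full quantification on a grayscale image: ROI selection,
#' binarization, density, longitudinal waveform, and spectral power of
#' regularity.
#'
#' @param image A [raster_image()].
#' @param roi_origin_um,roi_size_um ROI geometry passed to [select_roi()];
#'   `roi_size_um = NULL` uses the whole image.
#' @param method,fixed_threshold,invert Passed to [binarize()].
#' @param f0,band_halfwidth Passed to [regularity_power()].
#' @return A list of class `striation_metrics` with `density`,
#'   `regularity_power`, `f_peak`, `threshold`, `spectrum`, and the ROI
#'   geometry.
#' @export
striation_metrics <- function(image, roi_origin_um = c(0, 0),
                              roi_size_um = NULL,
                              method = c("otsu", "fixed"),
                              fixed_threshold = NULL, invert = FALSE,
                              f0 = 0.5, band_halfwidth = 0.1) {
  stopifnot(inherits(image, "raster_image"))
  roi <- if (is.null(roi_size_um)) image else
    select_roi(image, roi_origin_um, roi_size_um)
  mask <- binarize(roi, method = method, fixed_threshold = fixed_threshold,
                   invert = invert)
  prof <- longitudinal_profile(mask)
  spec <- regularity_power(prof, roi$pixel_size_um, f0 = f0,
                           band_halfwidth = band_halfwidth)
  structure(list(density = staining_density(mask),
                 regularity_power = spec$regularity_power,
                 f_peak = spec$f_peak,
                 threshold = mask$threshold_used,
                 spectrum = spec,
                 roi_origin_um = roi_origin_um,
                 roi_size_um = if (is.null(roi_size_um))
                   rev(dim(image$data)) * image$pixel_size_um else roi_size_um),
            class = "striation_metrics")
}
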