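#' Detect T-tubule openings in an SICM height map
#'
#' Openings are depressions relative to a local reference surface. The
#' reference is a rolling-median surface (window `reference_window_um`),
#' which makes detection insensitive to overall offset, tilt remnants and
#' large-scale curvature of the cell surface. Every connected region whose
#' depth below the reference exceeds `depth_threshold_nm` and whose area is
#' at least `min_area_um2` yields one opening; regions whose centroids lie
#' closer than `min_separation_um` are merged into a single opening.
#'
#' @param scan A [topography_scan()].
#' @param depth_threshold_nm Minimum depth below the reference surface, nm.
#' @param min_area_um2 Minimum region area, um^2.
#' @param min_separation_um Centroid distance below which regions merge, um.
#' @param reference_window_um Rolling-median window, um.
#' @param smoothing_um Edge length of the box filter applied to the depth
#'   map before thresholding, um. Smoothing at roughly the opening radius
#'   acts as a matched filter: single-pixel roughness spikes are suppressed
#'   while genuine wells (several pixels wide) keep nearly their full depth.
#'   Set to 0 to threshold the raw depth map.
#' @return A data.frame with one row per opening and columns `x`, `y`
#'   (centroid, um from the scan's top-left corner, x rightward, y
#'   downward), `depth_nm` (scan median height minus region minimum) and
#'   `area_um2`. Zero rows for a featureless scan.
#' @export
detect_openings <- function(scan, depth_threshold_nm = 50,
                            min_area_um2 = 0.01, min_separation_um = 0.5,
                            reference_window_um = 2, smoothing_um = 0.3) {
  stopifnot(inherits(scan, "topography_scan"))
  h <- scan$height_nm
  px <- scan$pixel_size_um
  if (prod(dim(h)) * px^2 < 4) {
    stop("scan must cover at least 4 um^2", call. = FALSE)
  }
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      depth_nm = numeric(0), area_um2 = numeric(0))
  # rolling-median reference surface (EBImage::medianFilter works on [0,1])
  win_px <- max(1L, round(reference_window_um / px / 2))
  rng <- range(h)
  ref <- if (diff(rng) == 0) h else {
    scaled <- (h - rng[1]) / diff(rng)
    EBImage::medianFilter(scaled, size = win_px) * diff(rng) + rng[1]
  }
  depth <- ref - h
  smooth_px <- round(smoothing_um / px)
  if (smooth_px >= 2) {
    kern <- matrix(1 / smooth_px^2, smooth_px, smooth_px)
    depth <- EBImage::filter2(depth, kern, boundary = "replicate")
  }
  cand <- depth > depth_threshold_nm
  if (!any(cand)) return(empty)
  lab <- EBImage::bwlabel(matrix(as.numeric(cand), nrow(h), ncol(h)))
  n_lab <- max(lab)
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- (idx - 1L) %% nrow(h) + 1L
  cols <- (idx - 1L) %/% nrow(h) + 1L
  area_px <- tabulate(labs, n_lab)
  keep <- which(area_px * px^2 >= min_area_um2)
  if (!length(keep)) return(empty)
  cx <- tapply((cols - 0.5) * px, labs, mean)[as.character(keep)]
  cy <- tapply((rows - 0.5) * px, labs, mean)[as.character(keep)]
  surf_med <- stats::median(h)
  min_h <- tapply(h[idx], labs, min)[as.character(keep)]
  df <- data.frame(x = as.numeric(cx), y = as.numeric(cy),
                   depth_nm = surf_med - as.numeric(min_h),
                   area_um2 = area_px[keep] * px^2)
  # merge regions whose centroids are closer than min_separation_um
  if (nrow(df) > 1L && min_separation_um > 0) {
    d <- stats::dist(df[, c("x", "y")])
    grp <- stats::cutree(stats::hclust(d, method = "single"),
                         h = min_separation_um)
    if (max(grp) < nrow(df)) {
      w <- df$area_um2
      df <- do.call(rbind, lapply(split(seq_len(nrow(df)), grp), function(i) {
        data.frame(x = stats::weighted.mean(df$x[i], w[i]),
                   y = stats::weighted.mean(df$y[i], w[i]),
                   depth_nm = max(df$depth_nm[i]),
                   area_um2 = sum(df$area_um2[i]))
      }))
      rownames(df) <- NULL
    }
  }
  df[order(df$y, df$x), , drop = FALSE]
}

#' Opening density per 100 square micrometres
#'
#' @param openings Data.frame of openings from [detect_openings()] (only the
#'   row count is used).
#' @param scan The [topography_scan()] the openings came from.
#' @return Openings per 100 um^2: `count * 100 / scan area`.
#' @export
opening_density <- function(openings, scan) {
  stopifnot(inherits(scan, "topography_scan"))
  area <- prod(scan$scan_size_um)
  if (area <= 0) stop("scan area must be positive", call. = FALSE)
  nrow(openings) * 100 / area
}

# Count of points within `tol` of the best strip-centre line for a candidate
# direction: sliding window of width 2*tol over the projections onto the
# direction's normal.
max_points_in_window <- function(proj, width) {
  s <- sort(proj)
  j <- 1L
  best <- 1L
  for (i in seq_along(s)) {
    while (s[i] - s[j] > width) j <- j + 1L
    best <- max(best, i - j + 1L)
  }
  best
}

#' Classify a scan as regular from opening alignment
#'
#' A scan is "regular" when at least `min_aligned` openings are aligned:
#' some subset of that size fits a straight line with every member within
#' `lateral_tol_um` of it. The search is exact: a maximal set of points
#' lying in a strip of width `2 * lateral_tol_um` can always be achieved by
#' a strip that either has two points on one boundary (candidate direction =
#' the direction through a point pair) or one point on each boundary
#' (candidate directions = the two orientations at which a pair spans the
#' strip width exactly), so scanning those O(k^2) directions with a sliding
#' window over normal projections finds the true maximum.
#'
#' Optionally, `spacing_tol` additionally requires roughly even spacing
#' along the line (every consecutive gap within `spacing_tol` relative
#' deviation of the median gap); the default `NULL` imposes alignment only.
#'
#' @param openings Data.frame with columns `x`, `y` (um).
#' @param min_aligned Minimum aligned openings for a regular call
#'   (default 4).
#' @param lateral_tol_um Maximum lateral distance from the fitted line, um.
#' @param spacing_tol Optional relative tolerance on spacing regularity
#'   along the line, or `NULL` (default) to skip the spacing check.
#' @return A list with `regular` (logical) and `max_aligned_run` (size of
#'   the largest aligned subset).
#' @export
classify_regular <- function(openings, min_aligned = 4L,
                             lateral_tol_um = 0.35, spacing_tol = NULL) {
  k <- nrow(openings)
  if (k == 0L) return(list(regular = FALSE, max_aligned_run = 0L))
  x <- openings$x; y <- openings$y
  width <- 2 * lateral_tol_um
  best <- 1L
  if (k >= 2L) {
    pairs <- utils::combn(k, 2L)
    angles <- numeric(0)
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
      dx <- x[i2] - x[i1]; dy <- y[i2] - y[i1]
      len <- sqrt(dx^2 + dy^2)
      if (len == 0) next
      theta <- atan2(dy, dx)
      angles <- c(angles, theta)
      if (len > width) {
        # orientations at which this pair spans the strip exactly
        delta <- asin(width / len)
        angles <- c(angles, theta + delta, theta - delta)
      }
    }
    for (theta in unique(angles)) {
      proj <- -x * sin(theta) + y * cos(theta)  # onto the normal
      cnt <- max_points_in_window(proj, width)
      if (!is.null(spacing_tol) && cnt >= min_aligned) {
        cnt <- max_even_spaced(x, y, theta, width, spacing_tol)
      }
      best <- max(best, cnt)
    }
  }
  list(regular = best >= min_aligned, max_aligned_run = as.integer(best))
}

# Largest strip subset for direction theta that is also evenly spaced along
# the line (consecutive gaps within spacing_tol relative of the median gap).
max_even_spaced <- function(x, y, theta, width, spacing_tol) {
  proj_n <- -x * sin(theta) + y * cos(theta)
  proj_t <- x * cos(theta) + y * sin(theta)
  s <- sort(proj_n)
  best <- 1L
  for (lo in s) {
    inside <- which(proj_n >= lo & proj_n <= lo + width)
    if (length(inside) < 2L) next
    t_sorted <- sort(proj_t[inside])
    gaps <- diff(t_sorted)
    med <- stats::median(gaps)
    ok <- med > 0 && all(abs(gaps - med) <= spacing_tol * med)
    if (ok) best <- max(best, length(inside))
  }
  best
}

#' Full opening analysis of one scan
#'
#' Convenience wrapper running detection, density and regularity
#' classification.
#'
#' @param scan A [topography_scan()].
#' @param min_aligned,lateral_tol_um Passed to [classify_regular()].
#' @param ... Passed to [detect_openings()].
#' @return A list of class `opening_analysis` with `openings`, `count`,
#'   `density_per_100um2`, `regular` and `max_aligned_run`.
#' @export
opening_analysis <- function(scan, min_aligned = 4L, lateral_tol_um = 0.35,
                             ...) {
  op <- detect_openings(scan, ...)
  cl <- classify_regular(op, min_aligned = min_aligned,
                         lateral_tol_um = lateral_tol_um)
  structure(list(openings = op, count = nrow(op),
                 density_per_100um2 = opening_density(op, scan),
                 regular = cl$regular,
                 max_aligned_run = cl$max_aligned_run),
            class = "opening_analysis")
}
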