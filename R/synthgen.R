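#' Parameters for synthetic striated-staining images
#'
#' Describes an idealized striated fluorescence image: transverse stripes
#' (T-tubules / junctophilin / caveolin staining along Z-lines) spaced
#' `period_um` apart along the cell's long axis, degraded by a remodelling
#' parameter. `remodel_fraction = 0` gives a perfectly periodic pattern;
#' `remodel_fraction = 1` deletes every stripe segment, leaving unstructured
#' background. Remodelling removes stripe segments block-wise (contiguous
#' blocks along each stripe) to mimic the patchy loss of striation seen in
#' cultured cardiomyocytes, rather than thinning stripes pixel by pixel.
#'
#' Default geometry is 80 x 20 um at 0.1 um/px, so the conventional
#' 5 x 40 um analysis ROI always fits; the default 2.0 um period is the
#' adult-rat transverse T-tubule spacing.
#'
#' @param image_width_um,image_height_um Image extent in micrometres (width
#'   runs along the cell's long axis).
#' @param pixel_size_um Pixel size, um.
#' @param period_um Transverse stripe spacing, um.
#' @param stripe_width_um Stripe width, um; must be smaller than the period.
#' @param foreground_intensity,background_intensity Grayscale levels.
#' @param remodel_fraction Fraction of stripe area deleted, in `[0, 1]`.
#' @param remodel_block_um Length of the independently deleted stripe blocks
#'   along the stripe (short-axis direction), um.
#' @param additive_noise_sd Gaussian pixel noise SD (grayscale units).
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   images.
#' @return A list of class `striation_params`.
#' @export
striation_params <- function(image_width_um = 80, image_height_um = 20,
                             pixel_size_um = 0.1, period_um = 2.0,
                             stripe_width_um = 0.6,
                             foreground_intensity = 200,
                             background_intensity = 30,
                             remodel_fraction = 0, remodel_block_um = 1.0,
                             additive_noise_sd = 8, seed = NULL) {
  stopifnot_scalar_pos(image_width_um, "image_width_um")
  stopifnot_scalar_pos(image_height_um, "image_height_um")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(period_um, "period_um")
  stopifnot_scalar_pos(stripe_width_um, "stripe_width_um")
  if (stripe_width_um >= period_um) {
    stop("'stripe_width_um' must be smaller than 'period_um'", call. = FALSE)
  }
  if (remodel_fraction < 0 || remodel_fraction > 1) {
    stop("'remodel_fraction' must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "striation_params")
}

#' Generate a synthetic striated-staining image
#'
#' @param params A [striation_params()].
#' @return A [raster_image()] with the long axis along columns. The stripe
#'   centre positions (um) are attached as attribute `"stripe_centers_um"`.
#' @export
gen_striation_image <- function(params) {
  stopifnot(inherits(params, "striation_params"))
  p <- params
  with_seed(p$seed, {
    ncols <- round(p$image_width_um / p$pixel_size_um)
    nrows <- round(p$image_height_um / p$pixel_size_um)
    x_um <- (seq_len(ncols) - 0.5) * p$pixel_size_um
    y_um <- (seq_len(nrows) - 0.5) * p$pixel_size_um
    centers <- seq(p$period_um / 2, p$image_width_um, by = p$period_um)
    # distance of each column to the nearest stripe centre
    m <- (x_um - p$period_um / 2) %% p$period_um
    dist_to_center <- pmin(m, p$period_um - m)
    in_stripe_col <- dist_to_center < p$stripe_width_um / 2
    img <- matrix(p$background_intensity, nrows, ncols)
    stripe_mask <- matrix(FALSE, nrows, ncols)
    stripe_mask[, in_stripe_col] <- TRUE
    if (p$remodel_fraction > 0) {
      # delete contiguous blocks along each stripe independently
      block_px <- max(1L, round(p$remodel_block_um / p$pixel_size_um))
      block_id <- (seq_len(nrows) - 1L) %/% block_px
      n_blocks <- max(block_id) + 1L
      stripe_cols <- which(in_stripe_col)
      col_stripe <- round((x_um[stripe_cols] - p$period_um / 2) / p$period_um)
      for (s in unique(col_stripe)) {
        cols_s <- stripe_cols[col_stripe == s]
        kill <- stats::runif(n_blocks) < p$remodel_fraction
        stripe_mask[kill[block_id + 1L], cols_s] <- FALSE
      }
    }
    img[stripe_mask] <- p$foreground_intensity
    if (p$additive_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, p$additive_noise_sd),
                          nrows, ncols)
    }
    out <- raster_image(img, p$pixel_size_um, long_axis = "columns")
    attr(out, "stripe_centers_um") <- centers
    out
  })
}

#' Parameters for synthetic SICM topography scans
#'
#' Describes a scanning ion conductance microscopy height map of the
#' cardiomyocyte surface: a gently rough surface carrying well-shaped
#' depressions at T-tubule opening sites. With `arrangement = "regular_rows"`
#' the wells sit on a jittered lattice whose rows are `row_spacing_um` apart
#' (the Z-line spacing); with `"random"` they are placed uniformly with a
#' hard-core minimum separation. The number of wells is Poisson with mean
#' `opening_rate_per_100um2 * area / 100`.
#'
#' @param scan_size_um Scan edge length, um (square scans; default 10,
#'   giving the conventional 100 um^2 counting area).
#' @param pixel_size_um Lateral pixel size, um.
#' @param opening_rate_per_100um2 Expected openings per 100 um^2.
#' @param opening_depth_nm Well depth at its centre, nm.
#' @param opening_radius_um Well radius, um; must be below half the row
#'   spacing so neighbouring wells stay resolvable.
#' @param row_spacing_um Spacing between rows of openings, um.
#' @param along_row_spacing_um Lattice spacing along each row, um.
#' @param row_jitter_um SD of the Gaussian jitter applied to each well
#'   position, um.
#' @param surface_roughness_sd_nm SD of the background surface roughness, nm.
#' @param arrangement `"regular_rows"` or `"random"`.
#' @param seed Integer seed.
#' @return A list of class `topography_params`.
#' @export
topography_params <- function(scan_size_um = 10, pixel_size_um = 0.1,
                              opening_rate_per_100um2 = 16.8,
                              opening_depth_nm = 150,
                              opening_radius_um = 0.3,
                              row_spacing_um = 2.0,
                              along_row_spacing_um = 1.5,
                              row_jitter_um = 0.1,
                              surface_roughness_sd_nm = 10,
                              arrangement = c("regular_rows", "random"),
                              seed = NULL) {
  stopifnot_scalar_pos(scan_size_um, "scan_size_um")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  if (opening_rate_per_100um2 < 0) {
    stop("'opening_rate_per_100um2' must be non-negative", call. = FALSE)
  }
  stopifnot_scalar_pos(opening_radius_um, "opening_radius_um")
  if (opening_radius_um >= row_spacing_um / 2) {
    stop("'opening_radius_um' must be below half the row spacing",
         call. = FALSE)
  }
  arrangement <- match.arg(arrangement)
  structure(as.list(environment()), class = "topography_params")
}

#' SICM topography scan container
#'
#' @param height_nm Numeric matrix of surface heights in nanometres (row 1 =
#'   top of the scan).
#' @param pixel_size_um Lateral pixel size, um.
#' @return An object of class `topography_scan`; `scan_size_um` holds the
#'   `c(width, height)` extent in um.
#' @export
topography_scan <- function(height_nm, pixel_size_um) {
  if (!is.matrix(height_nm) || !is.numeric(height_nm) ||
      any(!is.finite(height_nm))) {
    stop("'height_nm' must be a finite numeric matrix", call. = FALSE)
  }
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(height_nm = height_nm, pixel_size_um = pixel_size_um,
                 scan_size_um = c(ncol(height_nm), nrow(height_nm)) *
                   pixel_size_um),
            class = "topography_scan")
}

#' Generate a synthetic SICM topography scan
#'
#' @param params A [topography_params()].
#' @return A [topography_scan()]; programmed well centres (um, x/y from the
#'   top-left corner) are attached as attribute `"well_centers_um"` (a
#'   data.frame with columns `x`, `y`).
#' @export
gen_topography <- function(params) {
  stopifnot(inherits(params, "topography_params"))
  p <- params
  with_seed(p$seed, {
    n_px <- round(p$scan_size_um / p$pixel_size_um)
    area <- p$scan_size_um^2
    n_wells <- stats::rpois(1L, p$opening_rate_per_100um2 * area / 100)
    margin <- p$opening_radius_um
    centers <- if (n_wells == 0L) {
      data.frame(x = numeric(0), y = numeric(0))
    } else if (p$arrangement == "regular_rows") {
      rows_y <- seq(p$row_spacing_um / 2, p$scan_size_um - margin,
                    by = p$row_spacing_um)
      cols_x <- seq(p$along_row_spacing_um / 2, p$scan_size_um - margin,
                    by = p$along_row_spacing_um)
      lattice <- expand.grid(x = cols_x, y = rows_y)
      take <- sample.int(nrow(lattice), min(n_wells, nrow(lattice)))
      pts <- lattice[take, , drop = FALSE]
      pts$x <- pmin(pmax(pts$x + stats::rnorm(nrow(pts), 0, p$row_jitter_um),
                         margin), p$scan_size_um - margin)
      pts$y <- pmin(pmax(pts$y + stats::rnorm(nrow(pts), 0, p$row_jitter_um),
                         margin), p$scan_size_um - margin)
      pts
    } else {
      # hard-core placement: uniform draws, rejected below a minimum spacing
      min_d <- 2 * p$opening_radius_um + 0.2
      xs <- numeric(0); ys <- numeric(0); tries <- 0L
      while (length(xs) < n_wells && tries < 200L * n_wells) {
        cx <- stats::runif(1, margin, p$scan_size_um - margin)
        cy <- stats::runif(1, margin, p$scan_size_um - margin)
        if (!length(xs) || min(sqrt((xs - cx)^2 + (ys - cy)^2)) >= min_d) {
          xs <- c(xs, cx); ys <- c(ys, cy)
        }
        tries <- tries + 1L
      }
      data.frame(x = xs, y = ys)
    }
    h <- matrix(stats::rnorm(n_px * n_px, 0, p$surface_roughness_sd_nm),
                n_px, n_px)
    if (nrow(centers)) {
      x_um <- (seq_len(n_px) - 0.5) * p$pixel_size_um
      y_um <- (seq_len(n_px) - 0.5) * p$pixel_size_um
      for (i in seq_len(nrow(centers))) {
        dx2 <- (x_um - centers$x[i])^2
        dy2 <- (y_um - centers$y[i])^2
        r2 <- outer(dy2, dx2, `+`)
        well <- pmax(0, 1 - r2 / p$opening_radius_um^2)
        h <- h - p$opening_depth_nm * well
      }
    }
    out <- topography_scan(h, p$pixel_size_um)
    attr(out, "well_centers_um") <- centers
    out
  })
}

#' Parameters for simulated multi-channel gating currents
#'
#' Describes a cell-attached patch containing `n_channels` independent
#' two-state (closed-open) channels. Each channel gates as a continuous-time
#' Markov process with exponential dwell times (closed-to-open rate
#' `open_rate_per_s`, open-to-closed rate `close_rate_per_s`); the stationary
#' per-channel open probability is `open_rate / (open_rate + close_rate)`.
#' The observed current is the superposition of open channels times the
#' unitary current plus Gaussian noise. Channels gate only during the
#' activating voltage step and are closed at the holding potential, matching
#' L-type calcium channel behaviour at strongly negative holding potentials.
#'
#' @param n_channels Number of channels in the patch (integer >= 0).
#' @param open_rate_per_s,close_rate_per_s Transition rates, 1/s.
#' @param unitary_current_pA Single-channel current, pA (negative for inward
#'   calcium current).
#' @param noise_sd_pA Gaussian recording noise SD, pA.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param sweep_duration_s Sweep length, s.
#' @param n_sweeps Number of sweeps.
#' @param seed Integer seed.
#' @return A list of class `gating_params`.
#' @export
gating_params <- function(n_channels = 1L, open_rate_per_s = 50,
                          close_rate_per_s = 50,
                          unitary_current_pA = -1.2, noise_sd_pA = 0.15,
                          sampling_rate_hz = 5000, sweep_duration_s = 1,
                          n_sweeps = 1L, seed = NULL) {
  if (n_channels < 0 || n_channels != round(n_channels)) {
    stop("'n_channels' must be a non-negative integer", call. = FALSE)
  }
  if (n_channels > 0) {
    stopifnot_scalar_pos(open_rate_per_s, "open_rate_per_s")
    stopifnot_scalar_pos(close_rate_per_s, "close_rate_per_s")
  }
  stopifnot_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  stopifnot_scalar_pos(sweep_duration_s, "sweep_duration_s")
  structure(as.list(environment()), class = "gating_params")
}

#' Voltage-step protocol
#'
#' Holding and step potentials for cell-attached single-channel recordings.
#' Defaults are the conventional holding potential of -96.7 mV with an
#' activating step to -6.7 mV.
#'
#' @param holding_mV Holding potential, mV.
#' @param step_mV Step (test) potential, mV; must exceed the holding
#'   potential for an activating (depolarizing) step.
#' @param step_start_s Time of step onset within a sweep, s.
#' @param step_duration_s Step duration, s.
#' @return A list of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding_mV = -96.7, step_mV = -6.7,
                             step_start_s = 0.1, step_duration_s = 0.8) {
  if (step_mV <= holding_mV) {
    stop("'step_mV' must exceed 'holding_mV' for an activating step",
         call. = FALSE)
  }
  stopifnot_scalar_pos(step_duration_s, "step_duration_s")
  if (step_start_s < 0) stop("'step_start_s' must be >= 0", call. = FALSE)
  structure(list(holding_mV = holding_mV, step_mV = step_mV,
                 step_start_s = step_start_s,
                 step_duration_s = step_duration_s),
            class = "voltage_protocol")
}

#' Cell-attached patch recording container
#'
#' @param sweeps List of numeric current vectors (pA), all the same length.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param protocol A [voltage_protocol()].
#' @param labels Optional named list of grouping labels (e.g. `domain`
#'   "TT"/"crest", `group`, `agonist`); labels never affect computation.
#' @param pipette Optional [pipette_geometry()] of the recording pipette.
#' @return An object of class `patch_recording`.
#' @export
patch_recording <- function(sweeps, sampling_rate_hz, protocol,
                            labels = list(), pipette = NULL) {
  if (!is.list(sweeps) || !length(sweeps)) {
    stop("'sweeps' must be a non-empty list of numeric vectors", call. = FALSE)
  }
  len <- unique(vapply(sweeps, length, integer(1)))
  if (length(len) != 1L) {
    stop("all sweeps must have the same length", call. = FALSE)
  }
  stopifnot_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  stopifnot(inherits(protocol, "voltage_protocol"))
  structure(list(sweeps = sweeps, sampling_rate_hz = sampling_rate_hz,
                 protocol = protocol, labels = labels, pipette = pipette),
            class = "patch_recording")
}

# Simulate one channel's open intervals over [t0, t1] by exact exponential
# dwell sampling, returning the transition times (closed at t0).
sim_channel_transitions <- function(t0, t1, open_rate, close_rate) {
  t <- t0
  open <- FALSE
  trans <- numeric(0)
  while (t < t1) {
    dwell <- stats::rexp(1L, if (open) close_rate else open_rate)
    t <- t + dwell
    if (t < t1) trans <- c(trans, t)
    open <- !open
  }
  trans
}

#' Simulate a cell-attached patch recording
#'
#' Each channel follows an independent two-state Markov process during the
#' activating step, simulated by exact exponential dwell-time sampling and
#' then discretized to the sampling grid (the state at each sample time is
#' the state of the continuous-time process at that instant, which avoids
#' the transition-probability bias of per-sample simulation at coarse
#' rates). Channels are closed at the holding potential.
#'
#' @param gating A [gating_params()].
#' @param protocol A [voltage_protocol()]; the step must fit inside the
#'   sweep.
#' @param labels,pipette Passed through to the [patch_recording()].
#' @return A [patch_recording()]; the true per-sample open-channel counts are
#'   attached as attribute `"true_open_counts"` (list of integer vectors,
#'   one per sweep).
#' @export
gen_patch_trace <- function(gating, protocol = voltage_protocol(),
                            labels = list(), pipette = NULL) {
  stopifnot(inherits(gating, "gating_params"),
            inherits(protocol, "voltage_protocol"))
  g <- gating
  step_end <- protocol$step_start_s + protocol$step_duration_s
  if (step_end > g$sweep_duration_s) {
    stop("voltage step extends beyond the sweep duration", call. = FALSE)
  }
  if (g$n_channels > 0) {
    mean_dwell <- 1 / max(g$open_rate_per_s, g$close_rate_per_s)
    if (mean_dwell < 2 / g$sampling_rate_hz) {
      warning("mean dwell time below 2 samples; gating is under-resolved ",
              "at this sampling rate", call. = FALSE)
    }
  }
  with_seed(g$seed, {
    n_samp <- round(g$sweep_duration_s * g$sampling_rate_hz)
    t_samp <- (seq_len(n_samp) - 0.5) / g$sampling_rate_hz
    in_step <- t_samp >= protocol$step_start_s & t_samp < step_end
    step_idx <- which(in_step)
    sweeps <- vector("list", g$n_sweeps)
    truth <- vector("list", g$n_sweeps)
    for (s in seq_len(g$n_sweeps)) {
      counts <- integer(n_samp)
      if (g$n_channels > 0) {
        for (ch in seq_len(g$n_channels)) {
          trans <- sim_channel_transitions(protocol$step_start_s, step_end,
                                           g$open_rate_per_s,
                                           g$close_rate_per_s)
          # closed at step onset: open whenever an odd number of transitions
          # has occurred
          state <- findInterval(t_samp[step_idx], trans) %% 2L
          counts[step_idx] <- counts[step_idx] + state
        }
      }
      current <- counts * g$unitary_current_pA
      if (g$noise_sd_pA > 0) {
        current <- current + stats::rnorm(n_samp, 0, g$noise_sd_pA)
      }
      sweeps[[s]] <- current
      truth[[s]] <- counts
    }
    out <- patch_recording(sweeps, g$sampling_rate_hz, protocol,
                           labels = labels, pipette = pipette)
    attr(out, "true_open_counts") <- truth
    out
  })
}

#' Parameters for synthetic proximity-ligation images
#'
#' Describes a PLA image of a single cell: an elliptical cell mask containing
#' bright circular puncta on a dark background. Puncta centres are uniform
#' inside the mask (eroded by one puncta radius so every punctum lies fully
#' within the cell); by default puncta are placed without overlap so the
#' programmed covered area is exactly the sum of the disc areas.
#'
#' @param cell_axes_um Ellipse semi-axes `c(a, b)` of the cell mask, um.
#' @param puncta_count Number of puncta.
#' @param puncta_radius_um Punctum radius, um; must fit inside the cell.
#' @param pixel_size_um Pixel size, um.
#' @param foreground_intensity,background_intensity Grayscale levels.
#' @param noise_sd Gaussian pixel noise SD.
#' @param allow_overlap If `FALSE` (default), puncta are placed with centres
#'   at least two radii apart (error if that many non-overlapping puncta do
#'   not fit).
#' @param centers_um Optional data.frame with columns `x`, `y` (um from the
#'   image top-left) overriding random placement.
#' @param seed Integer seed.
#' @return A list of class `pla_params`.
#' @export
pla_params <- function(cell_axes_um = c(25, 8), puncta_count = 150L,
                       puncta_radius_um = 0.25, pixel_size_um = 0.1,
                       foreground_intensity = 220,
                       background_intensity = 20, noise_sd = 8,
                       allow_overlap = FALSE, centers_um = NULL,
                       seed = NULL) {
  if (length(cell_axes_um) != 2L || any(cell_axes_um <= 0)) {
    stop("'cell_axes_um' must be two positive semi-axes", call. = FALSE)
  }
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(puncta_radius_um, "puncta_radius_um")
  if (puncta_radius_um >= min(cell_axes_um)) {
    stop("'puncta_radius_um' must be smaller than the cell", call. = FALSE)
  }
  if (puncta_count < 0 || puncta_count != round(puncta_count)) {
    stop("'puncta_count' must be a non-negative integer", call. = FALSE)
  }
  structure(as.list(environment()), class = "pla_params")
}

#' Generate a synthetic proximity-ligation image and cell mask
#'
#' @param params A [pla_params()].
#' @return A list with elements `image` (a [raster_image()]) and `mask` (a
#'   [binary_mask()] of the cell area); the punctum centres are attached to
#'   the list as `centers_um`.
#' @export
gen_pla_image <- function(params) {
  stopifnot(inherits(params, "pla_params"))
  p <- params
  with_seed(p$seed, {
    a <- p$cell_axes_um[1]; b <- p$cell_axes_um[2]
    margin <- 1  # um of background around the cell
    w_um <- 2 * (a + margin); h_um <- 2 * (b + margin)
    ncols <- round(w_um / p$pixel_size_um)
    nrows <- round(h_um / p$pixel_size_um)
    cx <- w_um / 2; cy <- h_um / 2
    x_um <- (seq_len(ncols) - 0.5) * p$pixel_size_um
    y_um <- (seq_len(nrows) - 0.5) * p$pixel_size_um
    inside <- outer(((y_um - cy) / b)^2, ((x_um - cx) / a)^2, `+`) <= 1
    centers <- p$centers_um
    if (is.null(centers)) {
      r <- p$puncta_radius_um
      xs <- numeric(0); ys <- numeric(0); tries <- 0L
      max_tries <- 1000L * max(1L, p$puncta_count)
      while (length(xs) < p$puncta_count && tries < max_tries) {
        px <- stats::runif(1, -1, 1) * a; py <- stats::runif(1, -1, 1) * b
        ok <- (px / (a - r))^2 + (py / (b - r))^2 <= 1  # disc fully inside
        if (ok && !p$allow_overlap && length(xs)) {
          ok <- min(sqrt((xs - (cx + px))^2 + (ys - (cy + py))^2)) >= 2 * r
        }
        if (ok) { xs <- c(xs, cx + px); ys <- c(ys, cy + py) }
        tries <- tries + 1L
      }
      if (length(xs) < p$puncta_count) {
        stop("could not place the requested number of non-overlapping puncta",
             call. = FALSE)
      }
      centers <- data.frame(x = xs, y = ys)
    }
    img <- matrix(p$background_intensity, nrows, ncols)
    if (nrow(centers)) {
      for (i in seq_len(nrow(centers))) {
        d2 <- outer((y_um - centers$y[i])^2, (x_um - centers$x[i])^2, `+`)
        img[d2 <= p$puncta_radius_um^2] <- p$foreground_intensity
      }
    }
    if (p$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, p$noise_sd),
                          nrows, ncols)
    }
    list(image = raster_image(img, p$pixel_size_um, long_axis = "columns"),
         mask = binary_mask(inside, p$pixel_size_um),
         centers_um = centers)
  })
}
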