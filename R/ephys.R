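#' Pipette tip geometry from pipette resistance
#'
#' For a conical pipette tip, the access resistance is
#' `R_pipette = (pi * d/2 * tan(phi/2) * p)^-1`, where `d` is the tip inner
#' diameter, `phi` the tip cone angle and `p` the conductivity of the
#' pipette solution. Inverting for the diameter gives
#' `d = 2 / (R_pipette * pi * tan(phi/2) * p)`; `d` is strictly decreasing
#' in `R_pipette`.
#'
#' @param R_pipette Pipette resistance in ohms.
#' @param phi_deg Tip cone angle in degrees (default 3.8).
#' @param conductivity_S_per_m Pipette-solution conductivity in S/m
#'   (default 1.8).
#' @param d Tip inner diameter in metres (for [pipette_resistance()]).
#' @return `pipette_diameter()` returns the tip inner diameter in metres;
#'   `pipette_resistance()` returns the resistance in ohms;
#'   `pipette_geometry()` returns an object of class `pipette_geometry`
#'   holding resistance, angle, conductivity, diameter (m) and the patch
#'   area in um^2 under the flat-disc convention `pi * (d/2)^2`.
#' @export
pipette_diameter <- function(R_pipette, phi_deg = 3.8,
                             conductivity_S_per_m = 1.8) {
  stopifnot_scalar_pos(R_pipette, "R_pipette")
  stopifnot_scalar_pos(phi_deg, "phi_deg")
  stopifnot_scalar_pos(conductivity_S_per_m, "conductivity_S_per_m")
  2 / (R_pipette * pi * tan(phi_deg * pi / 360) * conductivity_S_per_m)
}

#' @rdname pipette_diameter
#' @export
pipette_resistance <- function(d, phi_deg = 3.8,
                               conductivity_S_per_m = 1.8) {
  stopifnot_scalar_pos(d, "d")
  stopifnot_scalar_pos(phi_deg, "phi_deg")
  stopifnot_scalar_pos(conductivity_S_per_m, "conductivity_S_per_m")
  1 / (pi * d / 2 * tan(phi_deg * pi / 360) * conductivity_S_per_m)
}

#' @rdname pipette_diameter
#' @export
pipette_geometry <- function(R_pipette, phi_deg = 3.8,
                             conductivity_S_per_m = 1.8) {
  d <- pipette_diameter(R_pipette, phi_deg, conductivity_S_per_m)
  d_um <- d * 1e6
  structure(list(R_pipette = R_pipette, phi_deg = phi_deg,
                 conductivity_S_per_m = conductivity_S_per_m,
                 d = d, d_um = d_um,
                 area_um2 = pi * (d_um / 2)^2),
            class = "pipette_geometry")
}

step_sample_index <- function(rec) {
  n <- length(rec$sweeps[[1L]])
  t_samp <- (seq_len(n) - 0.5) / rec$sampling_rate_hz
  pr <- rec$protocol
  which(t_samp >= pr$step_start_s &
          t_samp < pr$step_start_s + pr$step_duration_s)
}

# Unitary current from the all-points histogram of the step segment: spacing
# between the two lowest-|current| density modes.
estimate_unitary_current <- function(values) {
  d <- stats::density(values, n = 1024)
  ispeak <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (length(ispeak) < 2L) return(NA_real_)
  peaks <- d$x[ispeak]
  peaks <- peaks[order(abs(peaks))]
  peaks[2L] - peaks[1L]
}

#' Idealize a cell-attached recording by half-amplitude thresholding
#'
#' Reconstructs the per-sample number of simultaneously open channels from
#' each sweep. The baseline is the median of the pre-step segment; after
#' baseline subtraction each sample is assigned the integer level whose
#' current `k * i` is nearest (thresholds at `(k + 1/2) * i`, the
#' multi-level half-amplitude criterion). Dwells shorter than
#' `min_dwell_samples` are absorbed into the preceding level, suppressing
#' noise-driven flicker. If the unitary current is not supplied it is
#' estimated from the spacing of the first two modes of the all-points
#' histogram of the step segment.
#'
#' The result is flagged low-confidence when the unitary current does not
#' exceed three times the baseline noise SD (estimated from the pre-step
#' segment by the median absolute deviation), since level assignment is then
#' unreliable.
#'
#' @param rec A [patch_recording()].
#' @param unitary_current_pA Known single-channel current, pA (sign as
#'   recorded); `NULL` to estimate it from the data.
#' @param min_dwell_samples Minimum dwell length in samples (default 2).
#' @return A list of class `idealized_trace`: `open_counts` (list of integer
#'   vectors over the step segment, one per sweep), `step_index`,
#'   `unitary_current_pA`, `baseline_pA` (per sweep), `noise_sd_pA`, and
#'   `low_confidence`.
#' @export
idealize_trace <- function(rec, unitary_current_pA = NULL,
                           min_dwell_samples = 2L) {
  stopifnot(inherits(rec, "patch_recording"))
  step_idx <- step_sample_index(rec)
  if (!length(step_idx)) stop("no samples inside the voltage step", call. = FALSE)
  pre_idx <- seq_len(min(step_idx) - 1L)
  baselines <- vapply(rec$sweeps, function(s)
    if (length(pre_idx)) stats::median(s[pre_idx]) else 0, numeric(1))
  noise_sd <- stats::median(vapply(rec$sweeps, function(s)
    if (length(pre_idx) > 1L) stats::mad(s[pre_idx]) else NA_real_,
    numeric(1)), na.rm = TRUE)
  i_unit <- unitary_current_pA
  if (is.null(i_unit)) {
    all_step <- unlist(lapply(seq_along(rec$sweeps), function(k)
      rec$sweeps[[k]][step_idx] - baselines[k]))
    i_unit <- estimate_unitary_current(all_step)
    if (!is.finite(i_unit) || i_unit == 0) {
      stop("could not estimate the unitary current from the all-points ",
           "histogram; supply 'unitary_current_pA'", call. = FALSE)
    }
  }
  low_conf <- is.na(noise_sd) || abs(i_unit) <= 3 * noise_sd
  if (low_conf) {
    warning("unitary current does not exceed 3x the baseline noise SD; ",
            "idealization flagged low-confidence", call. = FALSE)
  }
  counts <- lapply(seq_along(rec$sweeps), function(k) {
    x <- rec$sweeps[[k]][step_idx] - baselines[k]
    lev <- pmax(0L, as.integer(round(x / i_unit)))
    enforce_min_dwell(lev, min_dwell_samples)
  })
  structure(list(open_counts = counts, step_index = step_idx,
                 unitary_current_pA = i_unit, baseline_pA = baselines,
                 noise_sd_pA = noise_sd, low_confidence = low_conf),
            class = "idealized_trace")
}

# Absorb runs shorter than min_dwell into the preceding level (the first run
# is kept regardless; a leading short run has no predecessor to absorb it).
enforce_min_dwell <- function(levels, min_dwell) {
  if (min_dwell <= 1L || length(levels) < 2L) return(levels)
  repeat {
    r <- rle(levels)
    short <- which(r$lengths < min_dwell)
    short <- short[short > 1L]
    if (!length(short)) break
    r$values[short] <- r$values[short - 1L]
    levels <- inverse.rle(r)
  }
  levels
}

#' Channel count of a patch
#'
#' The number of channels in the patch is estimated as the maximum number of
#' simultaneously open channels observed across all sweeps. This never
#' exceeds the true count and reaches it with probability approaching one as
#' recording length grows.
#'
#' @param ideal An [idealize_trace()] result.
#' @return Integer channel count (0 for an all-closed patch).
#' @export
estimate_channel_count <- function(ideal) {
  stopifnot(inherits(ideal, "idealized_trace"))
  as.integer(max(vapply(ideal$open_counts, max, numeric(1)), 0))
}

#' Open probability at the step potential
#'
#' `Po = (sum of open-channel counts over all step samples) /
#' (N * number of step samples)`, i.e. NPo divided by the channel count.
#'
#' @param ideal An [idealize_trace()] result.
#' @param N Channel count; default [estimate_channel_count()].
#' @return Po in `[0, 1]`, or `NA` for a patch with no channels.
#' @export
open_probability <- function(ideal, N = estimate_channel_count(ideal)) {
  stopifnot(inherits(ideal, "idealized_trace"))
  if (N < 1) return(NA_real_)
  total <- sum(vapply(ideal$open_counts, sum, numeric(1)))
  n_samples <- sum(vapply(ideal$open_counts, length, integer(1)))
  total / (N * n_samples)
}

#' Analyse one cell-attached patch end to end
#'
#' @param rec A [patch_recording()] (with `rec$pipette` set for density
#'   aggregation).
#' @param ... Passed to [idealize_trace()].
#' @return A list of class `patch_result`: `n_channels`, `po`,
#'   `unitary_current_pA`, `pipette`, `area_um2`, `d_um`, `labels`,
#'   `low_confidence`.
#' @export
analyze_patch <- function(rec, ...) {
  ideal <- idealize_trace(rec, ...)
  N <- estimate_channel_count(ideal)
  structure(list(n_channels = N, po = open_probability(ideal, N),
                 unitary_current_pA = ideal$unitary_current_pA,
                 pipette = rec$pipette,
                 area_um2 = if (!is.null(rec$pipette)) rec$pipette$area_um2
                 else NA_real_,
                 d_um = if (!is.null(rec$pipette)) rec$pipette$d_um
                 else NA_real_,
                 labels = rec$labels,
                 low_confidence = ideal$low_confidence),
            class = "patch_result")
}

#' Channel density over a set of patches
#'
#' Pools patches by dividing the total number of channels by the total
#' membrane sampled. Under the default `"area"` convention the membrane per
#' patch is the flat-disc area of the pipette tip, `pi * (d/2)^2`, and the
#' density is in channels/um^2; under the `"diameter"` convention the
#' channels are normalized to the sum of tip inner diameters, in
#' channels/um. Both conventions are reported in the field; the convention
#' used is recorded in the output.
#'
#' @param patches List of [analyze_patch()] results (each carrying a channel
#'   count and pipette geometry).
#' @param convention `"area"` (default) or `"diameter"`.
#' @return A list of class `channel_density_summary`: `density`,
#'   `total_channels`, `total_area_um2` or `total_diameter_um`,
#'   `n_patches`, `convention`.
#' @export
channel_density <- function(patches, convention = c("area", "diameter")) {
  convention <- match.arg(convention)
  if (!length(patches)) stop("empty patch list", call. = FALSE)
  n <- vapply(patches, function(p) as.numeric(p$n_channels), numeric(1))
  if (convention == "area") {
    denom <- vapply(patches, function(p) p$area_um2, numeric(1))
  } else {
    denom <- vapply(patches, function(p) p$d_um, numeric(1))
  }
  if (any(!is.finite(denom)) || sum(denom) <= 0) {
    stop("every patch needs a pipette geometry with positive tip size",
         call. = FALSE)
  }
  out <- list(density = sum(n) / sum(denom), total_channels = sum(n),
              n_patches = length(patches), convention = convention)
  if (convention == "area") out$total_area_um2 <- sum(denom)
  else out$total_diameter_um <- sum(denom)
  structure(out, class = "channel_density_summary")
}

#' Whole-cell recording container
#'
#' @param sweeps List of numeric current vectors (pA), one per step voltage.
#' @param step_mV Numeric vector of step voltages, one per sweep.
#' @param capacitance_pF Membrane capacitance, pF (measured at the rig).
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param step_start_s,step_duration_s Step timing within each sweep, s.
#' @return An object of class `whole_cell_recording`.
#' @export
whole_cell_recording <- function(sweeps, step_mV, capacitance_pF,
                                 sampling_rate_hz, step_start_s = 0.05,
                                 step_duration_s = 0.3) {
  if (length(sweeps) != length(step_mV)) {
    stop("one sweep per step voltage required", call. = FALSE)
  }
  stopifnot_scalar_pos(capacitance_pF, "capacitance_pF")
  stopifnot_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  structure(list(sweeps = sweeps, step_mV = step_mV,
                 capacitance_pF = capacitance_pF,
                 sampling_rate_hz = sampling_rate_hz,
                 step_start_s = step_start_s,
                 step_duration_s = step_duration_s),
            class = "whole_cell_recording")
}

#' Current-voltage analysis of a whole-cell recording
#'
#' For each step voltage, subtracts the pre-step baseline (median), takes
#' the peak inward current during the step (the minimum of the baseline-
#' subtracted trace) and divides by the cell capacitance to obtain the
#' current density in pA/pF.
#'
#' @param rec A [whole_cell_recording()].
#' @return Data.frame with columns `step_mV`, `peak_pA`,
#'   `density_pA_per_pF`, ordered by voltage.
#' @export
iv_analysis <- function(rec) {
  stopifnot(inherits(rec, "whole_cell_recording"))
  n <- length(rec$sweeps[[1L]])
  t_samp <- (seq_len(n) - 0.5) / rec$sampling_rate_hz
  in_step <- t_samp >= rec$step_start_s &
    t_samp < rec$step_start_s + rec$step_duration_s
  pre <- t_samp < rec$step_start_s
  peaks <- vapply(rec$sweeps, function(s) {
    base <- if (any(pre)) stats::median(s[pre]) else 0
    min(s[in_step] - base)
  }, numeric(1))
  out <- data.frame(step_mV = rec$step_mV, peak_pA = peaks,
                    density_pA_per_pF = peaks / rec$capacitance_pF)
  out[order(out$step_mV), , drop = FALSE]
}
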