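test_that("pipette diameter follows the conical-tip resistance equation", {
  d100 <- pipette_diameter(100e6)
  expect_equal(d100, 1.0664e-7, tolerance = 1e-3)
  # doubling the resistance halves the diameter
  expect_equal(pipette_diameter(200e6), d100 / 2, tolerance = 1e-12)
  # algebraic round trip at machine precision
  for (R in c(5e6, 50e6, 100e6, 1e9)) {
    d <- pipette_diameter(R)
    expect_equal(pipette_resistance(d), R, tolerance = 1e-12)
  }
  # monotone decreasing
  Rs <- 10^seq(6, 9, length.out = 20)
  expect_true(all(diff(vapply(Rs, pipette_diameter, numeric(1))) < 0))
  expect_error(pipette_diameter(-1), "positive")
})

test_that("pipette_geometry reports the flat-disc patch area", {
  pg <- pipette_geometry(100e6)
  expect_equal(pg$area_um2, pi * (pg$d_um / 2)^2)
})

test_that("noiseless traces are idealized exactly", {
  g <- gating_params(n_channels = 1L, noise_sd_pA = 0,
                     unitary_current_pA = -1.2, sweep_duration_s = 2,
                     seed = 51)
  rec <- gen_patch_trace(g)
  ideal <- idealize_trace(rec, unitary_current_pA = -1.2,
                          min_dwell_samples = 1L)
  truth <- attr(rec, "true_open_counts")[[1]][ideal$step_index]
  expect_identical(ideal$open_counts[[1]], as.integer(truth))

  g3 <- gating_params(n_channels = 3L, noise_sd_pA = 0, seed = 52,
                      sweep_duration_s = 4)
  rec3 <- gen_patch_trace(g3)
  ideal3 <- idealize_trace(rec3, unitary_current_pA = -1.2,
                           min_dwell_samples = 1L)
  expect_equal(max(ideal3$open_counts[[1]]), 3)
})

test_that("idealization matches the threshold-grid oracle and ground truth", {
  g <- gating_params(n_channels = 2L, unitary_current_pA = -1.2,
                     noise_sd_pA = 1.2 / 5, sweep_duration_s = 5, seed = 53)
  rec <- gen_patch_trace(g)
  ideal <- idealize_trace(rec, unitary_current_pA = -1.2,
                          min_dwell_samples = 1L)
  x <- rec$sweeps[[1]][ideal$step_index] - ideal$baseline_pA[1]
  oracle <- threshold_grid_idealize(x, -1.2)
  expect_identical(ideal$open_counts[[1]], oracle)

  # with the minimum-dwell filter, agreement with ground truth >= 99%
  smoothed <- idealize_trace(rec, unitary_current_pA = -1.2)
  truth <- attr(rec, "true_open_counts")[[1]][smoothed$step_index]
  expect_gte(mean(smoothed$open_counts[[1]] == truth), 0.99)
})

test_that("the unitary current can be recovered from the histogram", {
  g <- gating_params(n_channels = 1L, open_rate_per_s = 40,
                     close_rate_per_s = 40, unitary_current_pA = -1.2,
                     noise_sd_pA = 0.15, sweep_duration_s = 5, seed = 54)
  rec <- gen_patch_trace(g)
  ideal <- idealize_trace(rec)
  expect_equal(ideal$unitary_current_pA, -1.2, tolerance = 0.1)
  expect_false(ideal$low_confidence)
})

test_that("an unresolvable unitary current is flagged, not hidden", {
  g <- gating_params(n_channels = 1L, unitary_current_pA = -0.3,
                     noise_sd_pA = 0.2, sweep_duration_s = 2, seed = 55)
  rec <- gen_patch_trace(g)
  expect_warning(
    ideal <- idealize_trace(rec, unitary_current_pA = -0.3),
    "low-confidence")
  expect_true(ideal$low_confidence)
})

test_that("channel count is the maximum simultaneous open level", {
  g <- gating_params(n_channels = 0L, sweep_duration_s = 1, seed = 56)
  rec <- gen_patch_trace(g)
  ideal <- idealize_trace(rec, unitary_current_pA = -1.2)
  expect_equal(estimate_channel_count(ideal), 0L)
  expect_true(is.na(open_probability(ideal)))

  g3 <- gating_params(n_channels = 3L, noise_sd_pA = 0, seed = 57,
                      sweep_duration_s = 4)
  ideal3 <- idealize_trace(gen_patch_trace(g3), unitary_current_pA = -1.2)
  expect_equal(estimate_channel_count(ideal3), 3L)
})

test_that("open probability is NPo over N", {
  fake <- structure(list(open_counts = list(c(rep(1L, 25), rep(0L, 75))),
                         step_index = 1:100), class = "idealized_trace")
  expect_equal(open_probability(fake, N = 1), 0.25)
  all_open <- structure(list(open_counts = list(rep(2L, 50)),
                             step_index = 1:50), class = "idealized_trace")
  expect_equal(open_probability(all_open, N = 2), 1)
})

test_that("simulated stationary Po is recovered by the estimator", {
  pos <- vapply(1:12, function(s) {
    g <- gating_params(n_channels = 1L, open_rate_per_s = 30,
                       close_rate_per_s = 70, sweep_duration_s = 10,
                       seed = 600 + s)
    rec <- gen_patch_trace(g, voltage_protocol(step_start_s = 0.1,
                                               step_duration_s = 9.8))
    open_probability(idealize_trace(rec, unitary_current_pA = -1.2))
  }, numeric(1))
  expect_lt(abs(mean(pos) - 0.3), 0.02)
})

test_that("channel density pools channels over membrane sampled", {
  mk_patch <- function(n, d_um) {
    structure(list(n_channels = n, d_um = d_um,
                   area_um2 = pi * (d_um / 2)^2), class = "patch_result")
  }
  one <- channel_density(list(mk_patch(3, 1)))
  expect_equal(one$density, 3 / (pi / 4), tolerance = 1e-12)

  none <- channel_density(list(mk_patch(0, 1), mk_patch(0, 2)))
  expect_equal(none$density, 0)

  # duplicating a patch leaves the density unchanged (ratio homogeneity)
  two <- channel_density(list(mk_patch(3, 1), mk_patch(3, 1)))
  expect_equal(two$density, one$density)

  # splitting one patch into two halves of area and channels is invariant
  whole <- channel_density(list(mk_patch(4, sqrt(2))))
  halves <- channel_density(list(mk_patch(2, 1), mk_patch(2, 1)))
  expect_equal(whole$density, halves$density, tolerance = 1e-12)

  # diameter convention: channels per um of summed tip diameter
  diam <- channel_density(list(mk_patch(3, 1.5)), convention = "diameter")
  expect_equal(diam$density, 2)
  expect_error(channel_density(list()), "empty")
})

test_that("iv analysis converts peak current to density", {
  fs <- 1e4
  n <- 0.4 * fs
  t_samp <- (seq_len(n) - 0.5) / fs
  mk_sweep <- function(peak) {
    s <- rep(0, n)
    in_step <- t_samp >= 0.05 & t_samp < 0.35
    s[in_step] <- peak * (t_samp[in_step] - 0.05) / 0.3
    s + 10  # constant offset removed by baseline subtraction
  }
  rec <- whole_cell_recording(list(mk_sweep(-500), mk_sweep(0)),
                              step_mV = c(10, 60), capacitance_pF = 100,
                              sampling_rate_hz = fs)
  iv <- iv_analysis(rec)
  expect_equal(iv$density_pA_per_pF[iv$step_mV == 10], -5, tolerance = 1e-2)
  expect_equal(iv$density_pA_per_pF[iv$step_mV == 60], 0, tolerance = 1e-12)
})

test_that("iv analysis recovers the peak of a Boltzmann-driven I-V", {
  # template: I(V) = G * (V - E_rev) / (1 + exp(-(V - V_half) / k_slope))
  fs <- 1e4; n <- 0.4 * fs
  t_samp <- (seq_len(n) - 0.5) / fs
  volts <- seq(-40, 60, by = 10)
  iv_template <- function(V) {
    2 * (V - 60) / (1 + exp(-(V - (-10)) / 6))
  }
  sweeps <- lapply(volts, function(V) {
    s <- rep(0, n)
    s[t_samp >= 0.05 & t_samp < 0.35] <- iv_template(V)
    s
  })
  rec <- whole_cell_recording(sweeps, volts, capacitance_pF = 120,
                              sampling_rate_hz = fs)
  iv <- iv_analysis(rec)
  v_peak_oracle <- volts[which.min(iv_template(volts))]
  expect_equal(iv$step_mV[which.min(iv$density_pA_per_pF)], v_peak_oracle)
})

test_that("end-to-end patch pipeline recovers a programmed channel density", {
  # patches with channel counts drawn at a fixed per-area intensity
  intensity <- 11.1  # channels per um^2
  pip <- pipette_geometry(30e6)
  set.seed(71)
  patches <- lapply(1:120, function(i) {
    n_true <- rpois(1, intensity * pip$area_um2)
    g <- gating_params(n_channels = n_true, open_rate_per_s = 60,
                       close_rate_per_s = 40, sweep_duration_s = 3,
                       seed = 7000 + i)
    rec <- gen_patch_trace(g, pipette = pip)
    analyze_patch(rec, unitary_current_pA = -1.2)
  })
  dens <- channel_density(patches)
  counts <- vapply(patches, `[[`, numeric(1), "n_channels")
  se <- sd(counts) / sqrt(length(counts)) / pip$area_um2
  expect_lt(abs(dens$density - intensity), 3 * se)
})
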