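test_that("all generators are deterministic under a fixed seed", {
  sp <- striation_params(seed = 7, remodel_fraction = 0.4)
  expect_identical(gen_striation_image(sp)$data, gen_striation_image(sp)$data)

  tp <- topography_params(seed = 7)
  expect_identical(gen_topography(tp)$height_nm, gen_topography(tp)$height_nm)

  gp <- gating_params(n_channels = 2L, seed = 7, sweep_duration_s = 0.5)
  proto <- voltage_protocol(step_start_s = 0.05, step_duration_s = 0.4)
  expect_identical(gen_patch_trace(gp, proto)$sweeps,
                   gen_patch_trace(gp, proto)$sweeps)

  pp <- pla_params(puncta_count = 20L, seed = 7)
  expect_identical(gen_pla_image(pp)$image$data, gen_pla_image(pp)$image$data)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(gen_striation_image(striation_params(seed = 99)))
  expect_identical(runif(1), before)
})

test_that("striation generator produces the programmed period", {
  p <- striation_params(seed = 1, remodel_fraction = 0, additive_noise_sd = 0)
  img <- gen_striation_image(p)
  prof <- colMeans(img$data)
  # brute-force autocorrelation: first non-zero-lag maximum at the period
  ac <- naive_autocorrelation(prof, max_lag = 40)
  # restrict to lags beyond the first zero crossing to skip the lag-0 peak
  first_neg <- which(ac < 0)[1]
  peak_lag <- (first_neg - 1) + which.max(ac[first_neg:41]) - 1
  expect_equal(peak_lag * p$pixel_size_um, 2.0, tolerance = 1e-8)
})

test_that("full remodelling erases the periodic component", {
  p <- striation_params(seed = 3, remodel_fraction = 1, additive_noise_sd = 0)
  img <- gen_striation_image(p)
  expect_true(all(img$data == p$background_intensity))
  prof <- colMeans(img$data)
  spec <- regularity_power(prof, p$pixel_size_um)
  expect_equal(spec$regularity_power, 0)
  expect_true(all(spec$power[-1] == 0))
})

test_that("striation parameter validation rejects degenerate geometry", {
  expect_error(striation_params(pixel_size_um = 0), "pixel_size_um")
  expect_error(striation_params(image_width_um = -1), "image_width_um")
  expect_error(striation_params(stripe_width_um = 3, period_um = 2),
               "smaller than")
  expect_error(striation_params(remodel_fraction = 1.2), "0, 1")
})

test_that("topography generator matches its programmed opening rate", {
  # rate 0: flat surface up to roughness
  flat <- gen_topography(topography_params(seed = 5,
                                           opening_rate_per_100um2 = 0,
                                           surface_roughness_sd_nm = 10))
  expect_equal(nrow(attr(flat, "well_centers_um")), 0L)
  expect_lt(diff(range(flat$height_nm)), 10 * 12)

  # Poisson sampling: mean programmed count over seeds ~= rate * area / 100
  rate <- 17
  counts <- vapply(1:200, function(s) {
    sc <- gen_topography(topography_params(seed = s,
                                           opening_rate_per_100um2 = rate,
                                           surface_roughness_sd_nm = 0))
    nrow(attr(sc, "well_centers_um"))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - rate), 3 * se + 1e-9)
})

test_that("topography parameter validation enforces resolvable wells", {
  expect_error(topography_params(opening_radius_um = 1.2,
                                 row_spacing_um = 2), "half the row spacing")
  expect_error(topography_params(opening_rate_per_100um2 = -1),
               "non-negative")
})

test_that("gating simulation has the analytic stationary open fraction", {
  # no channels: pure Gaussian noise around zero
  g0 <- gen_patch_trace(gating_params(n_channels = 0L, noise_sd_pA = 0.2,
                                      sweep_duration_s = 2, seed = 8))
  expect_lt(abs(mean(g0$sweeps[[1]])), 0.02)

  # symmetric rates, one channel, long sweep: open fraction ~= 0.5
  g <- gating_params(n_channels = 1L, open_rate_per_s = 40,
                     close_rate_per_s = 40, sweep_duration_s = 20,
                     noise_sd_pA = 0, seed = 9)
  rec <- gen_patch_trace(g, voltage_protocol(step_start_s = 0.1,
                                             step_duration_s = 19.8))
  truth <- attr(rec, "true_open_counts")[[1]]
  t_samp <- (seq_along(truth) - 0.5) / g$sampling_rate_hz
  frac <- mean(truth[t_samp >= 0.1 & t_samp < 19.9])
  # SE of the time average of a two-state process: 2*p*(1-p)*tau/T
  tau <- 1 / 80
  se <- sqrt(2 * 0.25 * tau / 19.8)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("noiseless superposition takes exactly the n+1 current levels", {
  g <- gating_params(n_channels = 3L, noise_sd_pA = 0,
                     unitary_current_pA = -1.2, sweep_duration_s = 2,
                     seed = 10)
  rec <- gen_patch_trace(g)
  expect_true(all(rec$sweeps[[1]] %in% (0:3 * -1.2)))
  # closed at holding potential
  pre <- rec$sweeps[[1]][1:(0.1 * g$sampling_rate_hz - 1)]
  expect_true(all(pre == 0))
})

test_that("under-resolved gating triggers a warning", {
  g <- gating_params(n_channels = 1L, open_rate_per_s = 5000,
                     close_rate_per_s = 5000, sampling_rate_hz = 1000,
                     sweep_duration_s = 0.5, seed = 1)
  expect_warning(gen_patch_trace(g, voltage_protocol(step_duration_s = 0.3)),
                 "under-resolved")
})

test_that("pla generator covers exactly the programmed disc area", {
  # zero puncta: nothing above a mid threshold
  p0 <- gen_pla_image(pla_params(puncta_count = 0L, noise_sd = 0, seed = 2))
  r0 <- pla_density(p0$image, p0$mask, method = "fixed",
                    fixed_threshold = 120)
  expect_equal(r0$density, 0)

  # disjoint discs, no noise: density equals pixelized disc area / mask area
  pp <- pla_params(puncta_count = 40L, noise_sd = 0, seed = 6)
  out <- gen_pla_image(pp)
  res <- pla_density(out$image, out$mask)
  px <- pp$pixel_size_um
  x_um <- (seq_len(ncol(out$image$data)) - 0.5) * px
  y_um <- (seq_len(nrow(out$image$data)) - 0.5) * px
  disc_px <- sum(vapply(seq_len(nrow(out$centers_um)), function(i) {
    d2 <- outer((y_um - out$centers_um$y[i])^2,
                (x_um - out$centers_um$x[i])^2, `+`)
    sum(d2 <= pp$puncta_radius_um^2)
  }, numeric(1)))
  expect_equal(res$density, disc_px / sum(out$mask$data))
  # and close to the continuous-geometry ratio
  a_cont <- nrow(out$centers_um) * pi * pp$puncta_radius_um^2
  expect_equal(res$density, a_cont / res$cell_area_um2, tolerance = 0.05)
})

test_that("pla parameter validation rejects puncta larger than the cell", {
  expect_error(pla_params(puncta_radius_um = 9, cell_axes_um = c(20, 8)),
               "smaller than the cell")
})
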