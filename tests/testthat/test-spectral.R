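test_that("detrending removes constants, ramps and preserves oscillations", {
  expect_equal(detrend_trace(rep(5, 4)), rep(0, 4))
  expect_equal(detrend_trace(c(0, 1, 2, 3)), rep(0, 4), tolerance = 1e-12)
  t <- seq(0, 2, length.out = 251)
  s <- sin(2 * pi * 12 * t)
  d <- detrend_trace(s + 7 + 3 * t)
  expect_equal(mean(d), 0, tolerance = 1e-10)
  expect_gt(stats::cor(d, s), 0.999)
  expect_error(detrend_trace(5), "at least 2")
})

test_that("power spectra peak at planted frequencies and respect Parseval", {
  fs <- 125
  t <- (0:499) / fs
  x <- sin(2 * pi * 12 * t)
  sp <- power_spectrum(detrend_trace(x), fs)
  expect_equal(sp$frequencies_hz[which.max(sp$power)], 12, tolerance = 0.13)
  expect_true(all(sp$power >= 0))
  expect_lte(max(sp$frequencies_hz), fs / 2)
  # all-zero trace -> all-zero power
  expect_true(all(power_spectrum(rep(0, 64), fs)$power == 0))
  # weak 8 Hz + strong 15 Hz -> argmax at 15
  y <- 0.2 * sin(2 * pi * 8 * t) + sin(2 * pi * 15 * t)
  spy <- power_spectrum(detrend_trace(y), fs)
  expect_equal(spy$frequencies_hz[which.max(spy$power)], 15, tolerance = 0.13)
  # Parseval: unwindowed, unpadded power (plus DC) sums to signal energy
  set.seed(1)
  z <- stats::rnorm(128)
  spz <- power_spectrum(z, fs, window = "none", pad = FALSE)
  dc <- Mod(sum(z))^2 / length(z)
  expect_equal(sum(spz$power) + dc, sum(z^2), tolerance = 1e-8)
  expect_error(power_spectrum(rep(1, 4), fs), "at least 8")
})

test_that("dominant frequency picks in-band peaks and flags flat spectra", {
  fs <- 125
  t <- (0:499) / fs
  sp <- power_spectrum(detrend_trace(sin(2 * pi * 12 * t)), fs)
  df <- dominant_frequency(sp, c(3, 30))
  expect_true(df$included)
  expect_equal(df$frequency_hz, 12, tolerance = 0.13)
  # 2 Hz drift + 12 Hz beat: band excludes the drift
  x <- 3 * sin(2 * pi * 2 * t) + sin(2 * pi * 12 * t)
  df2 <- dominant_frequency(power_spectrum(detrend_trace(x), fs), c(3, 30))
  expect_equal(df2$frequency_hz, 12, tolerance = 0.13)
  # flat spectrum: no peak
  flat <- structure(list(frequencies_hz = seq(0.5, 62.5, by = 0.5),
                         power = rep(1, 125), frame_rate_fps = 125, n = 250),
                    class = "PowerSpectrum")
  expect_false(dominant_frequency(flat, c(3, 30))$included)
  expect_true(is.na(dominant_frequency(flat, c(3, 30))$frequency_hz))
  expect_error(dominant_frequency(sp, c(3, 80)), "Nyquist")
  expect_error(dominant_frequency(sp, c(10.01, 10.02)), "empty")
})

test_that("the CBF map recovers planted frequencies within a spectral bin", {
  sim <- simulate_field(small_sim_config(n_frames = 250L, noise_sd = 10))
  cm <- cbf_map(sim$video)
  planted <- sim$ground_truth$cells$frequency_hz
  bin <- 125 / 512  # padded resolution
  expect_gt(cm$n_included, 50)
  expect_equal(cm$median_cbf_hz, planted, tolerance = 2 * bin)
  expect_equal(cm$mean_cbf_hz, planted, tolerance = 0.5)
  expect_true(all(cm$dominant_frequency_hz[cm$included] >= 3 &
                  cm$dominant_frequency_hz[cm$included] <= 30))
})

test_that("two planted frequencies give an in-between mean and bimodal map", {
  # two cells at 10 and 14 Hz: simulate two single-cell fields and abut them
  mk <- function(f, seed) simulate_field(simulation_config(
    field_width_px = 96, field_height_px = 96, n_cells = 1, n_frames = 250,
    noise_sd = 0, frequency_distribution = list(mean_hz = f, sd_hz = 0),
    direction_distribution = list(mean_angle_rad = 1, concentration = 1e6),
    seed = seed))$video$frames
  v <- array(0, dim = c(250, 96, 192))
  v[, , 1:96] <- mk(10, 1)
  v[, , 97:192] <- mk(14, 2)
  cm <- cbf_map(video_stack(v, 125))
  expect_gt(cm$mean_cbf_hz, 10)
  expect_lt(cm$mean_cbf_hz, 14)
  f <- cm$dominant_frequency_hz[cm$included]
  expect_gt(mean(abs(f - 10) < 0.5), 0.3)
  expect_gt(mean(abs(f - 14) < 0.5), 0.3)
  expect_lt(mean(abs(f - 12) < 0.5), 0.05)
})

test_that("noise-only videos are essentially excluded and flagged", {
  set.seed(11)
  v <- video_stack(array(stats::rnorm(80 * 64 * 64, 100, 10),
                         c(80, 64, 64)), 125)
  cm <- cbf_map(v)
  # the inclusion rule is a statistical test: allow a handful of
  # false-positive pixels, never more than 0.1%
  expect_lt(cm$n_included / length(cm$included), 0.001)
  v0 <- video_stack(array(100, c(16, 8, 8)), 125)
  cm0 <- cbf_map(v0)
  expect_equal(cm0$n_included, 0)
  expect_true(is.na(cm0$mean_cbf_hz))
})

test_that("CBF estimates are invariant under affine intensity rescaling", {
  sim <- simulate_field(small_sim_config(n_frames = 125L, noise_sd = 10))
  cm1 <- cbf_map(sim$video)
  v2 <- video_stack(2.5 * sim$video$frames + 40, 125)
  cm2 <- cbf_map(v2)
  expect_identical(cm1$included, cm2$included)
  expect_identical(cm1$dominant_frequency_hz, cm2$dominant_frequency_hz)
})

test_that("frequencies at or beyond Nyquist are never reported, and undersampling aliases", {
  # a 12 Hz beat recorded at 20 fps is above Nyquist (10 Hz): the default
  # band is refused outright, and with a legal band the 12 Hz beat shows
  # up aliased (|12 - 20| = 8 Hz), never as 12 Hz
  cfg <- simulation_config(field_width_px = 96, field_height_px = 96,
                           n_cells = 1, n_frames = 600, noise_sd = 0,
                           frame_rate_fps = 120,
                           frequency_distribution = list(mean_hz = 12,
                                                         sd_hz = 0),
                           direction_distribution = list(
                             mean_angle_rad = 1, concentration = 1e6),
                           seed = 5)
  sim <- simulate_field(cfg)
  sub <- sim$video$frames[seq(1, 600, by = 6), , ]  # resample at 20 fps
  v12 <- video_stack(sub, 20)
  expect_error(cbf_map(v12, band_hz = c(3, 30)), "Nyquist")
  cm <- cbf_map(v12, band_hz = c(3, 9.9))
  expect_gt(cm$n_included, 10)
  expect_true(all(cm$dominant_frequency_hz[cm$included] < 10))
  expect_equal(cm$median_cbf_hz, 8, tolerance = 0.5)
})
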