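test_that("the beat axis of a single simulated cell is recovered within 10 degrees", {
  for (ang in c(30, 145)) {
    sim <- simulate_field(small_sim_config(
      direction_distribution = list(mean_angle_rad = deg2rad(ang),
                                    concentration = 1e6)))
    roi <- rois_from_ground_truth(sim$ground_truth)[[1]]
    mo <- motion_energy_orientation(sim$video, roi)
    truth <- rad2deg(sim$ground_truth$cells$angle_rad) %% 180
    expect_lt(ang_diff_deg(rad2deg(mo$axis_rad), truth, period = 180), 10)
    expect_gt(mo$anisotropy, 0.1)
  }
})

test_that("a static video yields a flagged-absent axis with zero anisotropy", {
  v <- video_stack(array(100, c(20, 48, 48)), 125)
  mo <- motion_energy_orientation(v, cell_roi(1, 24, 24, 15))
  expect_true(is.na(mo$axis_rad))
  expect_equal(mo$anisotropy, 0)
  dr <- resolve_direction(v, cell_roi(1, 24, 24, 15), mo$axis_rad)
  expect_true(is.na(dr$direction_rad))
})

test_that("axis estimates are pi-periodic: theta and theta + 180 agree", {
  base <- list(direction_distribution = list(mean_angle_rad = deg2rad(40),
                                             concentration = 1e6))
  s1 <- simulate_field(do.call(small_sim_config, base))
  base$direction_distribution$mean_angle_rad <- deg2rad(220)
  s2 <- simulate_field(do.call(small_sim_config, base))
  m1 <- motion_energy_orientation(s1$video, rois_from_ground_truth(s1$ground_truth)[[1]])
  m2 <- motion_energy_orientation(s2$video, rois_from_ground_truth(s2$ground_truth)[[1]])
  expect_lt(ang_diff_deg(rad2deg(m1$axis_rad), rad2deg(m2$axis_rad), 180), 3)
})

test_that("rotating the video by 90 degrees rotates the estimated axis by 90", {
  sim <- simulate_field(small_sim_config(
    direction_distribution = list(mean_angle_rad = deg2rad(20),
                                  concentration = 1e6)))
  roi <- rois_from_ground_truth(sim$ground_truth)[[1]]
  mo <- motion_energy_orientation(sim$video, roi)
  v <- sim$video$frames
  T_ <- dim(v)[1]; H <- dim(v)[2]; W <- dim(v)[3]
  vr <- array(0, c(T_, W, H))
  for (t in seq_len(T_)) vr[t, , ] <- t(v[t, , ])[, H:1]
  roir <- cell_roi(1, roi$y_px, H + 1 - roi$x_px, roi$radius_px)
  mor <- motion_energy_orientation(video_stack(vr, 125), roir)
  expect_lt(ang_diff_deg(rad2deg(mor$axis_rad),
                         rad2deg(mo$axis_rad) + 90, 180), 1)
})

test_that("power-stroke direction is recovered for asymmetric beats", {
  for (ang in c(210, 75)) {
    sim <- simulate_field(small_sim_config(
      power_stroke_fraction = 0.25,
      direction_distribution = list(mean_angle_rad = deg2rad(ang),
                                    concentration = 1e6)))
    roi <- rois_from_ground_truth(sim$ground_truth)[[1]]
    mo <- motion_energy_orientation(sim$video, roi)
    dr <- resolve_direction(sim$video, roi, mo$axis_rad)
    truth <- rad2deg(sim$ground_truth$cells$angle_rad)
    expect_false(is.na(dr$direction_rad))
    expect_gte(dr$asymmetry, 1.2)
    expect_lt(ang_diff_deg(rad2deg(dr$direction_rad), truth, 360), 10)
    # consistency: the direction reduces to the input axis modulo pi
    expect_lt(ang_diff_deg(rad2deg(dr$direction_rad) %% 180,
                           rad2deg(mo$axis_rad), 180), 1e-6)
  }
})

test_that("a time-symmetric beat is flagged ambiguous", {
  sim <- simulate_field(small_sim_config(
    power_stroke_fraction = 0.5, seed = 2,
    direction_distribution = list(mean_angle_rad = deg2rad(210),
                                  concentration = 1e6)))
  roi <- rois_from_ground_truth(sim$ground_truth)[[1]]
  mo <- motion_energy_orientation(sim$video, roi)
  dr <- resolve_direction(sim$video, roi, mo$axis_rad)
  expect_true(is.na(dr$direction_rad))
})

test_that("mirroring the video reflects the resolved direction", {
  sim <- simulate_field(small_sim_config(
    power_stroke_fraction = 0.25,
    direction_distribution = list(mean_angle_rad = deg2rad(20),
                                  concentration = 1e6)))
  roi <- rois_from_ground_truth(sim$ground_truth)[[1]]
  mo <- motion_energy_orientation(sim$video, roi)
  dr <- resolve_direction(sim$video, roi, mo$axis_rad)
  W <- dim(sim$video$frames)[3]
  vm <- video_stack(sim$video$frames[, , W:1], 125)
  roim <- cell_roi(1, W + 1 - roi$x_px, roi$y_px, roi$radius_px)
  mom <- motion_energy_orientation(vm, roim)
  drm <- resolve_direction(vm, roim, mom$axis_rad)
  expect_lt(ang_diff_deg(rad2deg(drm$direction_rad),
                         180 - rad2deg(dr$direction_rad), 360), 1)
})

test_that("estimate_angles aggregates cells and reports flagged ones", {
  cfg <- simulation_config(field_width_px = 220, field_height_px = 220,
                           n_cells = 5, n_frames = 125, noise_sd = 5,
                           power_stroke_fraction = 0.25,
                           direction_distribution = list(
                             mean_angle_rad = 1, concentration = 50),
                           seed = 6)
  sim <- simulate_field(cfg)
  rois <- rois_from_ground_truth(sim$ground_truth)
  a <- suppressWarnings(estimate_angles(sim$video, rois, mode = "axis"))
  expect_s3_class(a, "AngleSet")
  expect_equal(a$mode, "axis")
  expect_equal(a$source, "estimated")
  expect_true(all(a$angles_rad >= 0 & a$angles_rad < pi))
  det <- attr(a, "details")
  expect_equal(nrow(det), 5)
})

test_that("manual angle tables load with modular reduction and warnings", {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(cell_id = 1:17,
                              angle_deg = c(370, 200, seq(10, 150, 10))),
                   p, row.names = FALSE)
  a <- load_manual_angles(p, mode = "direction")
  expect_equal(rad2deg(a$angles_rad[1]), 10, tolerance = 1e-9)
  expect_equal(rad2deg(a$angles_rad[2]), 200, tolerance = 1e-9)
  expect_equal(a$source, "manual")
  ax <- suppressWarnings(load_manual_angles(p, mode = "axis"))
  expect_equal(rad2deg(ax$angles_rad[2]), 20, tolerance = 1e-9)
  expect_warning(load_manual_angles(p, mode = "axis"), "180")
  # 14 rows trip the below-minimum warning
  p14 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(cell_id = 1:14, angle_deg = seq(5, 70, 5)),
                   p14, row.names = FALSE)
  expect_warning(load_manual_angles(p14, "direction"), "15 ciliated cells")
  # malformed tables are rejected with named columns
  pbad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = 1, ang = 2), pbad, row.names = FALSE)
  expect_error(load_manual_angles(pbad, "direction"), "angle_deg")
})
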