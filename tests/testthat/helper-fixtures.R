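# Small simulated fields used across the suite. Fixture sizes are kept
# modest (96 x 96 px, 1-2 cells) so each test runs in seconds; the
# acceptance tests exercise full-size fields.

small_sim_config <- function(...) {
  defaults <- list(
    field_width_px = 96L, field_height_px = 96L,
    n_cells = 1L, n_frames = 125L, noise_sd = 0,
    frequency_distribution = list(mean_hz = 12, sd_hz = 0),
    direction_distribution = list(mean_angle_rad = deg2rad(30),
                                  concentration = 1e6),
    seed = 3L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# smallest absolute angular difference under a period (degrees)
ang_diff_deg <- function(a, b, period = 360) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# brute-force circular statistics via complex arithmetic: the
# independent oracle for Eqs. R = |mean(exp(i theta))|, S = sqrt(-2 ln R)
oracle_R <- function(theta) Mod(mean(exp(1i * theta)))
oracle_S <- function(theta) sqrt(-2 * log(oracle_R(theta)))
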