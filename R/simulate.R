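#' Configuration for a synthetic ciliated-field video
#'
#' Defines the study conditions for a simulated high-speed recording of
#' an epithelial surface bearing multiciliated cells. The defaults
#' emulate a typical human tracheal field of view: 420 x 340 px at
#' 0.5 um/px (approximately 210 x 170 um) holding 20 ciliated cells,
#' recorded at 125 fps for 250 frames (2 s), with beat frequencies
#' centred on 12 Hz.
#'
#' Each cell carries a planted beat direction drawn from a von Mises
#' distribution; `concentration` (kappa) controls field-level
#' coordination — large kappa (e.g. 400) emulates a healthy,
#' well-coordinated epithelium, kappa near 0 a disorganized one. Cilia
#' are modelled as rigid rods pivoting about fixed basal points in the
#' vertical plane containing the beat direction; the video renders their
#' top-view projection, so each cilium appears as a bright segment lying
#' along the beat direction whose projected length oscillates — extending
#' rapidly during the power stroke and retracting slowly during recovery
#' (see [cilium_waveform()]). Neighbouring cells beat with a metachronal
#' phase offset proportional to their position along the beat direction.
#'
#' @param field_width_px,field_height_px Field size in pixels.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param frame_rate_fps Acquisition rate in frames per second.
#' @param n_frames Number of frames (>= 2).
#' @param n_cells Number of ciliated cells (>= 1), placed without overlap.
#' @param cell_radius_um Radius of a cell's apical surface in um.
#' @param cilia_per_cell Number of cilia rendered per cell.
#' @param cilium_length_um Cilium length in um; must be < 4 * cell radius.
#' @param direction_distribution List with `mean_angle_rad` and
#'   `concentration` (von Mises kappa >= 0; 0 = uniform directions).
#' @param axial_mode If `TRUE`, planted angles are axes in `[0, pi)`
#'   rather than directions in `[0, 2*pi)`.
#' @param frequency_distribution List with `mean_hz` and `sd_hz` (>= 0);
#'   per-cell beat frequencies are normal draws, truncated to stay
#'   positive and below Nyquist. The mean must be below Nyquist
#'   (`frame_rate_fps / 2`).
#' @param stroke_amplitude_rad Half-angle of the cilium's angular sweep in
#'   its stroke plane, in `(0, pi/4]`.
#' @param power_stroke_fraction Fraction of the beat cycle spent in the
#'   fast power stroke, in (0, 1). 0.5 gives a time-symmetric beat with
#'   no resolvable power-stroke direction.
#' @param metachronal_phase_gradient_rad_per_um Phase advance per um of
#'   position along the beat direction (0 = all cells in phase).
#' @param cilium_phase_jitter_rad Standard deviation of the random
#'   per-cilium phase offset around its cell's phase (default 0.8 rad).
#'   Cilia within one cell are coordinated but not clones; without this
#'   intracellular desynchronization the rendered cell interior is
#'   almost static (perfectly superposed rods cancel in the temporal
#'   difference), which no real recording shows.
#' @param background_level Constant background intensity (arbitrary
#'   units, >= 0).
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#'   The default (15, i.e. 10% of the peak cilium intensity) is moderate
#'   shot-like noise for epifluorescence.
#' @param cilium_intensity Peak added intensity of a rendered cilium.
#' @param seed Integer seed; identical (config, seed) pairs reproduce
#'   bit-identical videos.
#' @return An object of class `SimulationConfig` (a validated list).
#' @seealso [simulate_field()]
#' @export
simulation_config <- function(field_width_px = 420L,
                              field_height_px = 340L,
                              pixel_size_um = 0.5,
                              frame_rate_fps = 125,
                              n_frames = 250L,
                              n_cells = 20L,
                              cell_radius_um = 4,
                              cilia_per_cell = 30L,
                              cilium_length_um = 6,
                              direction_distribution = list(
                                mean_angle_rad = 0, concentration = 8),
                              axial_mode = FALSE,
                              frequency_distribution = list(
                                mean_hz = 12, sd_hz = 0.5),
                              stroke_amplitude_rad = 0.6,
                              power_stroke_fraction = 0.3,
                              metachronal_phase_gradient_rad_per_um = 0.1,
                              cilium_phase_jitter_rad = 0.8,
                              background_level = 100,
                              noise_sd = 15,
                              cilium_intensity = 150,
                              seed = 1L) {
  cfg <- list(
    field_width_px = as.integer(field_width_px),
    field_height_px = as.integer(field_height_px),
    pixel_size_um = pixel_size_um,
    frame_rate_fps = frame_rate_fps,
    n_frames = as.integer(n_frames),
    n_cells = as.integer(n_cells),
    cell_radius_um = cell_radius_um,
    cilia_per_cell = as.integer(cilia_per_cell),
    cilium_length_um = cilium_length_um,
    direction_distribution = direction_distribution,
    axial_mode = isTRUE(axial_mode),
    frequency_distribution = frequency_distribution,
    stroke_amplitude_rad = stroke_amplitude_rad,
    power_stroke_fraction = power_stroke_fraction,
    metachronal_phase_gradient_rad_per_um = metachronal_phase_gradient_rad_per_um,
    cilium_phase_jitter_rad = cilium_phase_jitter_rad,
    background_level = background_level,
    noise_sd = noise_sd,
    cilium_intensity = cilium_intensity,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(field_width_px >= 8L, field_height_px >= 8L,
              pixel_size_um > 0, frame_rate_fps > 0, n_frames >= 2L,
              n_cells >= 1L, cell_radius_um > 0, cilia_per_cell >= 1L,
              cilium_length_um > 0, background_level >= 0, noise_sd >= 0,
              cilium_intensity > 0)
    if (!is.finite(direction_distribution$mean_angle_rad) ||
        direction_distribution$concentration < 0) {
      stop("direction_distribution needs finite mean_angle_rad and concentration >= 0")
    }
    if (frequency_distribution$sd_hz < 0) stop("frequency sd_hz must be >= 0")
    if (cilium_phase_jitter_rad < 0) stop("cilium_phase_jitter_rad must be >= 0")
    if (frequency_distribution$mean_hz >= frame_rate_fps / 2) {
      stop(sprintf(
        "planted mean frequency (%g Hz) must be below the Nyquist frequency (%g Hz = frame_rate/2)",
        frequency_distribution$mean_hz, frame_rate_fps / 2))
    }
    if (cilium_length_um >= cell_radius_um * 4) {
      stop("cilium_length_um must be < 4 * cell_radius_um")
    }
    if (!(stroke_amplitude_rad > 0 && stroke_amplitude_rad <= pi / 4)) {
      stop("stroke_amplitude_rad must lie in (0, pi/4]")
    }
    if (!(power_stroke_fraction > 0 && power_stroke_fraction < 1)) {
      stop("power_stroke_fraction must lie in (0, 1)")
    }
  })
  invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(
    "SimulationConfig: %d x %d px (%.1f x %.1f um), %d cells, %d frames @ %g fps\n",
    x$field_width_px, x$field_height_px,
    x$field_width_px * x$pixel_size_um, x$field_height_px * x$pixel_size_um,
    x$n_cells, x$n_frames, x$frame_rate_fps))
  cat(sprintf("  beat: %g +/- %g Hz, kappa = %g, power-stroke fraction %g, seed %d\n",
              x$frequency_distribution$mean_hz, x$frequency_distribution$sd_hz,
              x$direction_distribution$concentration,
              x$power_stroke_fraction, x$seed))
  invisible(x)
}

#' Angular deflection of a beating cilium
#'
#' Piecewise-linear (sawtooth-like) beat cycle in the cilium's stroke
#' plane: starting at `+stroke_amplitude_rad` at cycle phase 0, the
#' deflection sweeps linearly to `-stroke_amplitude_rad` during the power
#' stroke (the first `power_stroke_fraction` of the cycle) and returns
#' linearly during the remainder (the recovery stroke). The waveform is
#' continuous and periodic with period `1/frequency_hz`. With
#' `power_stroke_fraction = 0.5` it is an even triangle wave.
#'
#' @param t Time(s) in seconds (vectorized).
#' @param frequency_hz Beat frequency in Hz (> 0).
#' @param phase_rad Phase offset in radians (2*pi = one full cycle).
#' @param stroke_amplitude_rad Half-angle of the sweep.
#' @param power_stroke_fraction Fraction of the cycle in the fast stroke,
#'   in (0, 1).
#' @return Angular deflection(s) in radians, in
#'   `[-stroke_amplitude_rad, +stroke_amplitude_rad]`.
#' @export
#' @examples
#' cilium_waveform(0, 12, 0, 0.5, 0.25)        # +0.5: cycle start
#' cilium_waveform(1 / 12, 12, 0, 0.5, 0.25)   # +0.5: one full period later
cilium_waveform <- function(t, frequency_hz, phase_rad,
                            stroke_amplitude_rad, power_stroke_fraction) {
  check_finite(t, "t")
  check_finite(frequency_hz, "frequency_hz")
  check_finite(phase_rad, "phase_rad")
  check_finite(stroke_amplitude_rad, "stroke_amplitude_rad")
  check_finite(power_stroke_fraction, "power_stroke_fraction")
  stopifnot(all(frequency_hz > 0),
            all(power_stroke_fraction > 0 & power_stroke_fraction < 1))
  u <- (t * frequency_hz + phase_rad / (2 * pi)) %% 1
  A <- stroke_amplitude_rad
  p <- power_stroke_fraction
  ifelse(u < p,
         A - 2 * A * u / p,            # fast power stroke: +A -> -A
         -A + 2 * A * (u - p) / (1 - p)) # slow recovery: -A -> +A
}

# internal: projected extension fraction (0..1) of the rod at deflection
# delta. The pivot happens in the vertical plane containing the beat
# direction; gamma = A - delta is the tilt from vertical, so the top-view
# projected length is L * sin(gamma) / sin(2A): zero at the recovery end
# (cilium upright), maximal at full power-stroke extension.
projected_extension <- function(delta, stroke_amplitude_rad) {
  gam <- stroke_amplitude_rad - delta
  pmax(0, sin(gam) / sin(2 * stroke_amplitude_rad))
}

#' Simulate a high-speed video of a field of beating ciliated cells
#'
#' Places `n_cells` non-overlapping cells in the field, plants a beat
#' direction (von Mises), beat frequency (truncated normal) and
#' metachronal phase for each, renders every frame with anti-aliased
#' cilium segments on a constant background, and finally adds Gaussian
#' noise. The returned ground truth records the planted per-cell
#' parameters so downstream estimators can be validated by recovery.
#'
#' Rendering uses mathematical image coordinates: x increases to the
#' right, y increases upward, angles counterclockwise from +x.
#' Deterministic: the same (config, seed) pair yields a bit-identical
#' video and ground truth.
#'
#' @param config A [simulation_config()].
#' @return A list with components `video` (a [video_stack()]) and
#'   `ground_truth` (class `GroundTruth`: `cells` data frame with columns
#'   `cell_id`, `x_px`, `y_px`, `angle_rad`, `frequency_hz`, `phase_rad`,
#'   plus `axial_mode` and the echoed `config`).
#' @export
#' @examples
#' sim <- simulate_field(simulation_config(
#'   field_width_px = 96, field_height_px = 96, n_cells = 2,
#'   n_frames = 50, noise_sd = 0, seed = 7))
#' dim(sim$video$frames)
simulate_field <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  validate_simulation_config(config)
  cfg <- config
  set.seed(cfg$seed)

  W <- cfg$field_width_px; H <- cfg$field_height_px
  r_px <- cfg$cell_radius_um / cfg$pixel_size_um
  L_px <- cfg$cilium_length_um / cfg$pixel_size_um

  centers <- place_cells(cfg$n_cells, W, H, r_px, margin = L_px + 1)

  # planted per-cell parameters
  kap <- cfg$direction_distribution$concentration
  mu <- cfg$direction_distribution$mean_angle_rad
  ang <- rvonmises(cfg$n_cells, mu, kap)
  if (cfg$axial_mode) ang <- wrap_angle(ang, pi)
  nyq <- cfg$frame_rate_fps / 2
  fr <- stats::rnorm(cfg$n_cells, cfg$frequency_distribution$mean_hz,
                     cfg$frequency_distribution$sd_hz)
  fr <- pmin(pmax(fr, 0.5), 0.95 * nyq)

  g <- cfg$metachronal_phase_gradient_rad_per_um
  u_cell <- cbind(cos(ang), sin(ang))
  proj_um <- (centers[, 1] * u_cell[, 1] + centers[, 2] * u_cell[, 2]) *
    cfg$pixel_size_um
  phase_cell <- wrap_angle(g * proj_um, 2 * pi)

  # per-cilium geometry: basal points uniform in the cell disk, small
  # orientation jitter about the cell's beat direction
  nc <- cfg$n_cells * cfg$cilia_per_cell
  cell_of <- rep(seq_len(cfg$n_cells), each = cfg$cilia_per_cell)
  rr <- r_px * sqrt(stats::runif(nc))
  aa <- stats::runif(nc, 0, 2 * pi)
  base_x <- centers[cell_of, 1] + rr * cos(aa)
  base_y <- centers[cell_of, 2] + rr * sin(aa)
  th_c <- ang[cell_of] + stats::rnorm(nc, 0, 0.05)
  ux <- cos(th_c); uy <- sin(th_c)
  phase_c <- wrap_angle(g * (base_x * ux + base_y * uy) * cfg$pixel_size_um +
                          stats::rnorm(nc, 0, cfg$cilium_phase_jitter_rad),
                        2 * pi)
  freq_c <- fr[cell_of]

  # Fixed sample points along each rod (spacing `step` px); per frame
  # only the per-sample mass changes with the projected extension:
  # fully covered samples carry mass `step`, the frontier sample a
  # partial mass. Fixed positions mean the bilinear splat pattern can be
  # prebuilt once as a sparse (pixels x samples) matrix, and each frame
  # is a single sparse matrix-vector product. This also renders the
  # advancing tip as a smooth sub-pixel ramp rather than a resampling
  # artifact.
  step <- 0.5
  n_s <- max(4L, as.integer(ceiling(L_px / step)))
  radii <- (seq_len(n_s) - 0.5) * (L_px / n_s)
  seg <- L_px / n_s
  px <- rep(base_x, times = n_s) + rep(radii, each = nc) * rep(ux, times = n_s)
  py <- rep(base_y, times = n_s) + rep(radii, each = nc) * rep(uy, times = n_s)
  S <- splat_matrix(px, py, W, H)

  frames <- array(0, dim = c(cfg$n_frames, H, W))
  tt <- (seq_len(cfg$n_frames) - 1L) / cfg$frame_rate_fps
  lower <- rep(radii - seg / 2, each = nc)
  for (f in seq_len(cfg$n_frames)) {
    delta <- cilium_waveform(tt[f], freq_c, phase_c,
                             cfg$stroke_amplitude_rad,
                             cfg$power_stroke_fraction)
    ext <- L_px * projected_extension(delta, cfg$stroke_amplitude_rad)
    cover <- pmin(pmax((rep(ext, times = n_s) - lower) / seg, 0), 1)
    dens <- as.vector(S %*% (cover * seg))
    frames[f, , ] <- cfg$background_level +
      cfg$cilium_intensity * matrix(dens, H, W)
  }
  if (cfg$noise_sd > 0) {
    frames <- frames + stats::rnorm(length(frames), 0, cfg$noise_sd)
    frames[frames < 0] <- 0
  }

  video <- video_stack(frames, frame_rate_fps = cfg$frame_rate_fps,
                       pixel_size_um = cfg$pixel_size_um)
  gt <- structure(
    list(cells = data.frame(cell_id = seq_len(cfg$n_cells),
                            x_px = centers[, 1], y_px = centers[, 2],
                            angle_rad = ang, frequency_hz = fr,
                            phase_rad = phase_cell),
         axial_mode = cfg$axial_mode,
         config = unclass(cfg)),
    class = "GroundTruth"
  )
  list(video = video, ground_truth = gt)
}

# internal: rejection placement of non-overlapping cell centers.
place_cells <- function(n, W, H, r_px, margin) {
  lo_x <- r_px + margin; hi_x <- W - r_px - margin
  lo_y <- r_px + margin; hi_y <- H - r_px - margin
  if (hi_x <= lo_x || hi_y <= lo_y) {
    stop("field too small for the requested cell radius and cilium length")
  }
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 4000L * n
  while (placed < n) {
    if (tries >= max_tries) {
      stop(sprintf("could not place %d non-overlapping cells in a %d x %d field",
                   n, W, H))
    }
    tries <- tries + 1L
    cx <- stats::runif(1, lo_x, hi_x)
    cy <- stats::runif(1, lo_y, hi_y)
    if (placed == 0L ||
        all((xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2 >=
            (2 * r_px)^2)) {
      placed <- placed + 1L
      xs[placed] <- cx; ys[placed] <- cy
    }
  }
  cbind(x = xs, y = ys)
}

# internal: anti-aliased splat operator. Maps per-sample masses at fixed
# continuous math coordinates (x right, y up) to an H*W pixel vector by
# bilinear weighting; returns a sparse (H*W x n_samples) matrix so a
# frame is rendered as a single matrix-vector product.
splat_matrix <- function(x, y, W, H) {
  n <- length(x)
  # math y (up) -> row index (down)
  r <- H + 1 - y
  c0 <- floor(x); r0 <- floor(r)
  fx <- x - c0; fy <- r - r0
  ii <- c(r0,     r0,     r0 + 1, r0 + 1)
  jj <- c(c0,     c0 + 1, c0,     c0 + 1)
  ww <- c((1 - fy) * (1 - fx), (1 - fy) * fx,
          fy * (1 - fx),       fy * fx)
  ss <- rep(seq_len(n), times = 4)
  keep <- ii >= 1 & ii <= H & jj >= 1 & jj <= W & ww > 0
  Matrix::sparseMatrix(i = (jj[keep] - 1L) * H + ii[keep], j = ss[keep],
                       x = ww[keep], dims = c(H * W, n))
}
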