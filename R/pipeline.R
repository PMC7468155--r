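#' Configuration of an end-to-end analysis run
#'
#' Ties the stages together: input (a [simulation_config()] to generate,
#' or a TIFF path to load), ROI source, spectral and motion parameters,
#' statistics parameters, and the output directory. Fully serializable;
#' [run_pipeline()] echoes the effective configuration into the output
#' directory so every reported statistic is traceable.
#'
#' @param input A [simulation_config()] or a path to a multi-page TIFF.
#' @param roi_source `"ground_truth"` (synthetic input only) or the path
#'   to a ROI CSV for [load_rois()].
#' @param mode Angular mode for the field statistics: `"direction"` or
#'   `"axis"`. In direction mode, if more than half the cells are
#'   ambiguous the run falls back to axis mode (recorded as a warning in
#'   the report).
#' @param band_hz,min_power_ratio Spectral parameters, see [cbf_map()].
#' @param asymmetry_threshold Motion parameter, see [resolve_direction()].
#' @param bin_width_deg Rose-diagram bin width, see [rose_histogram()].
#' @param frame_rate_fps Frame-rate fallback for TIFF input without a
#'   sidecar.
#' @param roi_radius_px Default ROI radius for CSV ROI tables.
#' @param output_dir Directory for the run's outputs (created if
#'   needed); `NULL` computes in memory only.
#' @param seed Integer seed; overrides the seed inside a simulation
#'   input so the whole run is reproducible from this one value.
#' @param run_spectral,run_motion Stage toggles.
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(input,
                            roi_source = "ground_truth",
                            mode = c("direction", "axis"),
                            band_hz = c(3, 30),
                            min_power_ratio = 30,
                            asymmetry_threshold = 1.2,
                            bin_width_deg = 15,
                            frame_rate_fps = NULL,
                            roi_radius_px = 20,
                            output_dir = NULL,
                            seed = NULL,
                            run_spectral = TRUE,
                            run_motion = TRUE) {
  mode <- match.arg(mode)
  if (!(inherits(input, "SimulationConfig") ||
        (is.character(input) && length(input) == 1L))) {
    stop("`input` must be a SimulationConfig or a TIFF path")
  }
  structure(list(input = input, roi_source = roi_source, mode = mode,
                 band_hz = band_hz, min_power_ratio = min_power_ratio,
                 asymmetry_threshold = asymmetry_threshold,
                 bin_width_deg = bin_width_deg,
                 frame_rate_fps = frame_rate_fps,
                 roi_radius_px = roi_radius_px,
                 output_dir = output_dir,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 run_spectral = isTRUE(run_spectral),
                 run_motion = isTRUE(run_motion)),
            class = "PipelineConfig")
}

# internal: serializable echo of a pipeline config
config_as_list <- function(config) {
  cfg <- unclass(config)
  if (inherits(cfg$input, "SimulationConfig")) {
    cfg$input <- c(list(type = "simulation"), unclass(cfg$input))
  } else {
    cfg$input <- list(type = "tiff", path = cfg$input)
  }
  cfg
}

#' Run the full ciliary-motion analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or TIFF read),
#' per-pixel CBF spectral analysis, per-cell beat direction/axis
#' estimation, and circular statistics with a rose histogram. Any
#' stage's flagged conditions (static cells, ambiguous directions,
#' fewer than 15 cells, no included CBF pixels) are collected into the
#' report's `warnings`, never silently dropped. Deterministic: the same
#' configuration and seed reproduce identical numerical output, and
#' identical report files on disk.
#'
#' When `output_dir` is set, writes: `config.json` (effective config),
#' `report.json` (the run report), `angles.csv`, `rose.csv`,
#' `cbf_pixels.csv`, and `rose.png` (skipped with a recorded warning if
#' no graphics device is available).
#'
#' @param config A [pipeline_config()].
#' @return An object of class `RunReport`: list with `mean_cbf_hz`,
#'   `median_cbf_hz`, `n_pixels_included`, `angles` (data frame),
#'   `circular_summary`, `rose` (data frame), `warnings` (character),
#'   `provenance` (config hash, seed, package version), plus the
#'   in-memory `video`, `cbf`, `angle_set` for further analysis.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  # --- input stage -------------------------------------------------------
  gt <- NULL
  if (inherits(config$input, "SimulationConfig")) {
    sim_cfg <- config$input
    if (!is.null(config$seed)) {
      sim_cfg$seed <- config$seed
      validate_simulation_config(sim_cfg)
    }
    sim <- simulate_field(sim_cfg)
    video <- sim$video
    gt <- sim$ground_truth
  } else {
    video <- read_stack(config$input, frame_rate_fps = config$frame_rate_fps)
  }

  # --- ROIs --------------------------------------------------------------
  rois <- NULL
  if (config$run_motion) {
    if (identical(config$roi_source, "ground_truth")) {
      if (is.null(gt)) {
        stop("roi_source = \"ground_truth\" requires a simulation input; supply a ROI CSV")
      }
      rois <- rois_from_ground_truth(gt)
    } else {
      rois <- load_rois(config$roi_source, radius_px = config$roi_radius_px)
    }
  }

  # --- spectral stage ----------------------------------------------------
  cbf <- NULL
  if (config$run_spectral) {
    cbf <- cbf_map(video, band_hz = config$band_hz,
                   min_power_ratio = config$min_power_ratio)
    if (is.na(cbf$mean_cbf_hz)) {
      note("no pixel passed the CBF inclusion rule; mean CBF undefined")
    }
  }

  # --- motion + statistics stage -----------------------------------------
  angles <- NULL
  summ <- NULL
  rose <- NULL
  used_mode <- config$mode
  if (config$run_motion) {
    angles <- withCallingHandlers(
      estimate_angles(video, rois, mode = config$mode,
                      asymmetry_threshold = config$asymmetry_threshold,
                      warn_small = TRUE),
      warning = function(w) {
        note(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    flagged <- attr(angles, "flagged")
    n_amb <- sum(flagged$reason == "ambiguous power-stroke direction")
    if (config$mode == "direction" && n_amb > length(rois) / 2) {
      used_mode <- "axis"
      note(sprintf(
        "power-stroke direction ambiguous for %d of %d cells; falling back to axis mode",
        n_amb, length(rois)))
      angles <- withCallingHandlers(
        estimate_angles(video, rois, mode = "axis",
                        asymmetry_threshold = config$asymmetry_threshold,
                        warn_small = TRUE),
        warning = function(w) {
          note(conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
    summ <- summarize_angles(angles)
    rose <- rose_histogram(angles, bin_width_deg = config$bin_width_deg)
  }

  report <- structure(
    list(mean_cbf_hz = if (is.null(cbf)) NA_real_ else cbf$mean_cbf_hz,
         median_cbf_hz = if (is.null(cbf)) NA_real_ else cbf$median_cbf_hz,
         n_pixels_included = if (is.null(cbf)) 0L else cbf$n_included,
         mode = used_mode,
         angles = if (is.null(angles)) NULL else data.frame(
           cell_id = angles$cell_ids,
           angle_deg = rad2deg(angles$angles_rad)),
         circular_summary = summ,
         rose = if (is.null(rose)) NULL else as.data.frame(rose),
         warnings = warnings_log,
         provenance = list(seed = config$seed,
                           package_version = as.character(
                             utils::packageVersion("ciliamotion"))),
         video = video, cbf = cbf, angle_set = angles,
         ground_truth = gt),
    class = "RunReport"
  )

  if (!is.null(config$output_dir)) {
    report <- write_run_outputs(report, config)
  }
  report
}

# internal: serialize a run's outputs; returns the report with the config
# hash filled into provenance.
write_run_outputs <- function(report, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  cfg_path <- out("config.json")
  jsonlite::write_json(config_as_list(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  # hash only the analysis-relevant configuration: where the outputs
  # land must not change what the run computes
  canon <- config_as_list(config)
  canon$output_dir <- NULL
  canon_path <- tempfile(fileext = ".json")
  jsonlite::write_json(canon, canon_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  report$provenance$config_md5 <- unname(tools::md5sum(canon_path))
  unlink(canon_path)

  if (!is.null(report$angles)) {
    utils::write.csv(report$angles, out("angles.csv"), row.names = FALSE)
  }
  if (!is.null(report$rose)) {
    utils::write.csv(report$rose, out("rose.csv"), row.names = FALSE)
  }
  if (!is.null(report$cbf)) {
    utils::write.csv(as.data.frame(report$cbf), out("cbf_pixels.csv"),
                     row.names = FALSE)
  }

  json_report <- list(
    mean_cbf_hz = report$mean_cbf_hz,
    median_cbf_hz = report$median_cbf_hz,
    n_pixels_included = report$n_pixels_included,
    mode = report$mode,
    circular_summary = if (is.null(report$circular_summary)) NULL else list(
      n = report$circular_summary$n,
      mean_angle_deg = if (is.na(report$circular_summary$mean_angle_rad))
        NA_real_ else rad2deg(report$circular_summary$mean_angle_rad),
      R = report$circular_summary$R,
      S = report$circular_summary$S,
      mode = report$circular_summary$mode),
    n_cells = if (is.null(report$angles)) 0L else nrow(report$angles),
    warnings = report$warnings,
    provenance = report$provenance)
  jsonlite::write_json(json_report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)

  if (!is.null(report$angle_set)) {
    ok <- tryCatch({
      p <- plot_rose(rose_histogram(report$angle_set,
                                    bin_width_deg = config$bin_width_deg))
      suppressMessages(ggplot2::ggsave(out("rose.png"), p, width = 5,
                                       height = 5, dpi = 120))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      report$warnings <- c(report$warnings,
                           "rose plot could not be rendered (no graphics device)")
    }
  }
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport\n")
  if (!is.na(x$mean_cbf_hz)) {
    cat(sprintf("  mean CBF: %.2f Hz (median %.2f, %d px)\n", x$mean_cbf_hz,
                x$median_cbf_hz, x$n_pixels_included))
  }
  if (!is.null(x$circular_summary)) print(x$circular_summary)
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}
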