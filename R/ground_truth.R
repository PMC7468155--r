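#' Write simulation ground truth to JSON
#'
#' Serializes a `GroundTruth` object (per-cell planted directions,
#' frequencies and phases plus the echoed configuration) as JSON at full
#' double precision, so that [read_ground_truth()] round-trips
#' losslessly. An empty cell table is valid and produces a file with
#' zero records.
#'
#' @param gt A `GroundTruth` from [simulate_field()].
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "GroundTruth"))
  obj <- list(cells = gt$cells, axial_mode = gt$axial_mode,
              config = gt$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read simulation ground truth from JSON
#'
#' @param path Path written by [write_ground_truth()].
#' @return A `GroundTruth` object.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- obj$cells
  if (is.null(cells) || length(cells) == 0L || NROW(cells) == 0L) {
    cells <- data.frame(cell_id = integer(0), x_px = numeric(0),
                        y_px = numeric(0), angle_rad = numeric(0),
                        frequency_hz = numeric(0), phase_rad = numeric(0))
  }
  structure(list(cells = as.data.frame(cells),
                 axial_mode = isTRUE(obj$axial_mode),
                 config = obj$config),
            class = "GroundTruth")
}

#' Export the per-cell ground-truth table as CSV
#'
#' Writes the planted per-cell parameters with angles in degrees, header
#' `cell_id,x_px,y_px,angle_deg,frequency_hz,phase_deg` — the same layout
#' accepted by [load_manual_angles()] (which only needs `cell_id` and
#' `angle_deg`).
#'
#' @inheritParams write_ground_truth
#' @param path Output file path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(gt, path) {
  stopifnot(inherits(gt, "GroundTruth"))
  df <- data.frame(cell_id = gt$cells$cell_id,
                   x_px = gt$cells$x_px, y_px = gt$cells$y_px,
                   angle_deg = rad2deg(gt$cells$angle_rad),
                   frequency_hz = gt$cells$frequency_hz,
                   phase_deg = rad2deg(gt$cells$phase_rad))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d cells (%s mode)\n", nrow(x$cells),
              if (x$axial_mode) "axis" else "direction"))
  invisible(x)
}
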