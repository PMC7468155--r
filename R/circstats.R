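#' Construct a set of per-cell beat angles
#'
#' An `AngleSet` holds one angle per ciliated cell, tagged as either
#' *directional* data (a beat direction, 2pi-periodic) or *axial* data (a
#' beat axis, pi-periodic; used when the power-stroke side of the beat
#' cannot be resolved, as for very short cilia). Angles are stored in
#' radians in the fundamental domain of their mode: `[0, 2pi)` for
#' directions, `[0, pi)` for axes.
#'
#' Fields annotated this way are conventionally measured for at least 15
#' ciliated cells per field of view; a smaller set is accepted with a
#' warning, since dispersion statistics on very few cells are unstable.
#'
#' @param angles_rad Numeric vector of angles in radians (finite).
#' @param mode `"direction"` (2pi-periodic) or `"axis"` (pi-periodic).
#' @param cell_ids Optional vector of cell identifiers, parallel to
#'   `angles_rad`. Defaults to `seq_along(angles_rad)`.
#' @param source `"manual"` for user-annotated angles, `"estimated"` for
#'   angles measured from video by [estimate_angles()].
#' @param warn_small Emit the below-minimum warning when fewer than 15
#'   angles are supplied (default `TRUE`).
#' @return An object of class `AngleSet`: a list with elements
#'   `angles_rad`, `mode`, `cell_ids`, `source`.
#' @seealso [summarize_angles()], [rose_histogram()], [load_manual_angles()]
#' @export
#' @examples
#' a <- angle_set(deg2rad(c(10, 20, 350)), mode = "direction", warn_small = FALSE)
#' summarize_angles(a)
angle_set <- function(angles_rad, mode = c("direction", "axis"),
                      cell_ids = NULL, source = c("manual", "estimated"),
                      warn_small = TRUE) {
  mode <- match.arg(mode)
  source <- match.arg(source)
  check_finite(angles_rad, "angles_rad")
  if (length(angles_rad) < 1L) stop("`angles_rad` must contain at least one angle")
  if (is.null(cell_ids)) cell_ids <- seq_along(angles_rad)
  if (length(cell_ids) != length(angles_rad)) {
    stop("`cell_ids` must be parallel to `angles_rad`")
  }
  period <- if (mode == "axis") pi else 2 * pi
  out <- structure(
    list(angles_rad = wrap_angle(angles_rad, period),
         mode = mode, cell_ids = cell_ids, source = source),
    class = "AngleSet"
  )
  if (warn_small && length(angles_rad) < 15L) {
    warning(sprintf(
      "only %d angles; beat-direction dispersion is conventionally measured on at least 15 ciliated cells per field",
      length(angles_rad)), call. = FALSE)
  }
  out
}

#' @export
print.AngleSet <- function(x, ...) {
  cat(sprintf("AngleSet: %d %s angles (%s)\n", length(x$angles_rad),
              x$mode, x$source))
  cat("  degrees:", paste(signif(rad2deg(x$angles_rad), 4), collapse = ", "),
      "\n")
  invisible(x)
}

# internal: accept an AngleSet or a bare numeric vector of radians
as_angles <- function(x) {
  if (inherits(x, "AngleSet")) return(x$angles_rad)
  check_finite(x, "angles")
  if (length(x) < 1L) stop("need at least one angle")
  x
}

#' Unit vectors of a set of angles
#'
#' Maps each angle theta to the planar unit vector (cos theta, sin theta),
#' i.e. the complex number cos theta + i sin theta regarded as a point on
#' the unit circle. These unit vectors are the raw material of the mean
#' resultant length.
#'
#' @param x An [angle_set()] or numeric vector of angles in radians.
#' @return An n x 2 matrix with columns `x` (cosine) and `y` (sine); each
#'   row has unit norm.
#' @export
unit_vectors <- function(x) {
  th <- as_angles(x)
  cbind(x = cos(th), y = sin(th))
}

#' Mean resultant length of angular data
#'
#' `R = |(1/N) * sum_j v_j|`, the length of the average of the unit
#' vectors `v_j = cos(theta_j) + i sin(theta_j)`. `R = 1` when all angles
#' coincide and `R = 0` for a balanced (e.g. uniform) angular
#' distribution. R is invariant under rotation of all angles by a
#' constant.
#'
#' For an axial [angle_set()] the angles are doubled before averaging
#' (see [axial_summary()]); pass a numeric vector to compute the plain
#' directional R of the given values.
#'
#' @param x An [angle_set()] or numeric vector of angles in radians.
#' @return Mean resultant length in `[0, 1]`.
#' @export
#' @examples
#' resultant_length(deg2rad(c(0, 90)))  # sqrt(2)/2
resultant_length <- function(x) {
  th <- as_angles(x)
  if (inherits(x, "AngleSet") && x$mode == "axis") th <- 2 * th
  C <- mean(cos(th))
  S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  # snap within a few ulp of 1 (e.g. a single angle, or all angles
  # equal): S must then be exactly 0, not sqrt of a rounding residue
  if (r >= 1 - 4 * .Machine$double.eps) r <- 1
  min(r, 1)
}

# R below this is treated as exactly zero (balanced data); S is then +Inf
# and the mean angle undefined.
.zero_resultant_tol <- 1e-9

#' Circular standard deviation
#'
#' `S = sqrt(-2 ln R)` where R is the [resultant_length()]. S = 0 if and
#' only if all angles are equal (modulo the period); S diverges to +Inf
#' as R -> 0, and is returned as `Inf` when R is numerically zero
#' (balanced angles, e.g. three angles 120 degrees apart). S is the
#' standard disorganization measure for beat directionality: about 0.07
#' for a well-coordinated epithelium versus above 1 for a disorganized
#' one.
#'
#' @inheritParams resultant_length
#' @return Circular standard deviation in radians (non-negative, possibly
#'   `Inf`).
#' @export
#' @examples
#' circular_sd(deg2rad(c(0, 90)))   # 0.8325546
#' circular_sd(deg2rad(c(0, 180)))  # Inf: antipodal angles cancel
circular_sd <- function(x) {
  r <- resultant_length(x)
  if (r < .zero_resultant_tol) return(Inf)
  sqrt(-2 * log(r))
}

#' Circular mean angle
#'
#' The atan2 of the mean unit vector, i.e. the direction of the resultant.
#' Undefined (returned as `NA`) when the resultant length is numerically
#' zero. For an axial [angle_set()] the mean is computed on doubled angles
#' and halved back into `[0, pi)`.
#'
#' @inheritParams resultant_length
#' @return Mean angle in the mode's fundamental domain, or `NA` when
#'   undefined.
#' @export
circular_mean <- function(x) {
  th <- as_angles(x)
  axial <- inherits(x, "AngleSet") && x$mode == "axis"
  if (axial) th <- 2 * th
  C <- mean(cos(th))
  S <- mean(sin(th))
  if (sqrt(C^2 + S^2) < .zero_resultant_tol) return(NA_real_)
  m <- wrap_angle(atan2(S, C), 2 * pi)
  if (axial) wrap_angle(m / 2, pi) else m
}

#' Circular summary of an angle set
#'
#' Bundles the sample size, circular mean, mean resultant length R and
#' circular standard deviation S of an [angle_set()]. Directional sets
#' are summarized on the angles themselves; axial sets are dispatched to
#' [axial_summary()], which doubles the angles first. No small-sample
#' bias correction is applied to S.
#'
#' @param x An [angle_set()].
#' @return An object of class `CircularSummary`: a list with elements
#'   `n`, `mean_angle_rad` (`NA` when undefined), `R`, `S` (possibly
#'   `Inf`), `mode`.
#' @export
#' @examples
#' summarize_angles(angle_set(rep(1.2, 20), "direction"))  # R = 1, S = 0
summarize_angles <- function(x) {
  if (!inherits(x, "AngleSet")) stop("`x` must be an AngleSet")
  if (x$mode == "axis") return(axial_summary(x))
  structure(
    list(n = length(x$angles_rad),
         mean_angle_rad = circular_mean(x),
         R = resultant_length(x),
         S = circular_sd(x),
         mode = "direction"),
    class = "CircularSummary"
  )
}

#' Circular summary of axial (pi-periodic) data
#'
#' Axial data carry no arrowhead: theta and theta + pi are the same
#' observation. Dispersion is therefore computed on the doubled angles
#' 2*theta (which are 2pi-periodic), the standard angle-doubling device
#' for axial statistics. The reported R and S are those of the doubled
#' angles; the mean axis is the doubled-angle circular mean halved back
#' into `[0, pi)`. An S of 0 means all axes coincide modulo pi;
#' orthogonal axes (e.g. 0 and 90 degrees) are maximally spread and give
#' R = 0, S = Inf.
#'
#' @param x An [angle_set()] with `mode = "axis"`.
#' @return A `CircularSummary` with `mode = "axis"`.
#' @export
axial_summary <- function(x) {
  if (!inherits(x, "AngleSet") || x$mode != "axis") {
    stop("`x` must be an AngleSet with mode = \"axis\"")
  }
  structure(
    list(n = length(x$angles_rad),
         mean_angle_rad = circular_mean(x),  # axial-aware
         R = resultant_length(x),            # doubled internally
         S = circular_sd(x),
         mode = "axis"),
    class = "CircularSummary"
  )
}

#' @export
print.CircularSummary <- function(x, ...) {
  mean_txt <- if (is.na(x$mean_angle_rad)) "undefined"
              else sprintf("%.1f deg", rad2deg(x$mean_angle_rad))
  cat(sprintf("CircularSummary (%s): n = %d, mean = %s, R = %.4f, S = %s\n",
              x$mode, x$n, mean_txt,
              x$R, if (is.infinite(x$S)) "Inf" else sprintf("%.4f", x$S)))
  invisible(x)
}

#' @export
format.CircularSummary <- function(x, ...) {
  utils::capture.output(print(x))
}

#' Rose-diagram histogram of angular data
#'
#' Bins angles into uniform half-open sectors `[edge, edge + width)`
#' covering the mode's full period: `[0, 360)` degrees for directions,
#' `[0, 180)` for axes. An angle falling exactly on a bin edge is
#' assigned to the higher bin. Counts always sum to the number of input
#' angles.
#'
#' @param x An [angle_set()].
#' @param bin_width_deg Bin width in degrees; must divide the mode's
#'   period (360 or 180) evenly. Default 15 (24 direction bins or 12 axis
#'   bins).
#' @return An object of class `RoseHistogram`: list with `bin_edges_rad`
#'   (length nbins + 1), `counts`, `mode`, `bin_width_deg`, `n`.
#' @seealso [plot_rose()], [as.data.frame.RoseHistogram()]
#' @export
rose_histogram <- function(x, bin_width_deg = 15) {
  if (!inherits(x, "AngleSet")) stop("`x` must be an AngleSet")
  stopifnot(is.numeric(bin_width_deg), length(bin_width_deg) == 1L,
            bin_width_deg > 0)
  period_deg <- if (x$mode == "axis") 180 else 360
  nbins <- period_deg / bin_width_deg
  if (abs(nbins - round(nbins)) > 1e-9) {
    stop(sprintf("`bin_width_deg` (%g) must divide %d evenly",
                 bin_width_deg, period_deg))
  }
  nbins <- as.integer(round(nbins))
  deg <- rad2deg(x$angles_rad)
  # the small epsilon keeps angles that are exact bin edges up to
  # radian/degree roundoff in the higher bin, per the half-open rule
  idx <- floor(deg / bin_width_deg + 1e-9) + 1L
  idx[idx > nbins] <- 1L # roundoff at the period wraps to the first bin
  counts <- tabulate(idx, nbins)
  structure(
    list(bin_edges_rad = deg2rad(seq(0, period_deg, by = bin_width_deg)),
         counts = counts, mode = x$mode, bin_width_deg = bin_width_deg,
         n = length(x$angles_rad)),
    class = "RoseHistogram"
  )
}

#' @export
print.RoseHistogram <- function(x, ...) {
  cat(sprintf("RoseHistogram (%s): %d angles in %d bins of %g deg\n",
              x$mode, x$n, length(x$counts), x$bin_width_deg))
  invisible(x)
}

#' Rose histogram as a data frame
#'
#' @param x A [rose_histogram()].
#' @param ... Unused.
#' @return Data frame with columns `bin_start_deg`, `bin_end_deg`, `count`.
#' @export
as.data.frame.RoseHistogram <- function(x, ...) {
  edges <- rad2deg(x$bin_edges_rad)
  data.frame(bin_start_deg = edges[-length(edges)],
             bin_end_deg = edges[-1],
             count = x$counts)
}

#' Plot a rose diagram
#'
#' Renders the angular histogram as a polar sector plot with sector
#' *area* proportional to count (radius proportional to sqrt(count)),
#' the convention that keeps visual weight proportional to frequency.
#' Angles follow the mathematical convention: 0 degrees points right
#' (+x), angles increase counterclockwise. Axis-mode roses span 180
#' degrees; each axis is drawn once in `[0, 180)`.
#'
#' @param x A [rose_histogram()].
#' @param fill Sector fill colour.
#' @return A `ggplot` object.
#' @export
plot_rose <- function(x, fill = "steelblue") {
  if (!inherits(x, "RoseHistogram")) stop("`x` must be a RoseHistogram")
  df <- as.data.frame(x)
  df$mid <- (df$bin_start_deg + df$bin_end_deg) / 2
  df$radius <- sqrt(df$count)
  ggplot2::ggplot(df, ggplot2::aes(x = mid, y = radius)) +
    ggplot2::geom_col(width = x$bin_width_deg, fill = fill,
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, by = 30),
                                expand = c(0, 0),
                                oob = scales::oob_keep) +
    ggplot2::labs(x = NULL, y = expression(sqrt(count)),
                  title = sprintf("Rose diagram (%s, n = %d)", x$mode, x$n)) +
    ggplot2::theme_minimal()
}
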