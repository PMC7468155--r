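#' Circular region of interest around a ciliated cell
#'
#' @param cell_id Cell identifier.
#' @param x_px,y_px Center in mathematical image coordinates (x right,
#'   y up, in pixels).
#' @param radius_px ROI radius in pixels (> 0).
#' @return An object of class `CellROI`.
#' @export
cell_roi <- function(cell_id, x_px, y_px, radius_px) {
  stopifnot(is.finite(x_px), is.finite(y_px), radius_px > 0)
  structure(list(cell_id = cell_id, x_px = x_px, y_px = y_px,
                 radius_px = radius_px),
            class = "CellROI")
}

#' Build per-cell ROIs from simulation ground truth
#'
#' Circular ROIs centred on the planted cell centers, sized to cover the
#' cell body plus its cilia (radius = cell radius + cilium length, in
#' pixels), which is the footprint the motion energy actually occupies.
#'
#' @param gt A `GroundTruth` from [simulate_field()].
#' @param radius_px ROI radius override in pixels.
#' @return List of [cell_roi()] objects.
#' @export
rois_from_ground_truth <- function(gt, radius_px = NULL) {
  stopifnot(inherits(gt, "GroundTruth"))
  if (is.null(radius_px)) {
    cfg <- gt$config
    radius_px <- (cfg$cell_radius_um + cfg$cilium_length_um) / cfg$pixel_size_um
  }
  lapply(seq_len(nrow(gt$cells)), function(i) {
    cell_roi(gt$cells$cell_id[i], gt$cells$x_px[i], gt$cells$y_px[i],
             radius_px)
  })
}

# internal: crop an ROI's bounding box (+1 px gradient margin) out of the
# stack; returns frames (T x h x w), the mask of in-disk pixels on the
# crop, and the crop's coordinate offsets.
crop_roi <- function(video, roi) {
  d <- dim(video$frames)
  H <- d[2]; W <- d[3]
  # math y -> row
  r_c <- H + 1 - roi$y_px
  rad <- roi$radius_px
  r0 <- max(2L, floor(r_c - rad)); r1 <- min(H - 1L, ceiling(r_c + rad))
  c0 <- max(2L, floor(roi$x_px - rad)); c1 <- min(W - 1L, ceiling(roi$x_px + rad))
  if (r1 < r0 || c1 < c0) stop("ROI lies outside the frame bounds")
  sub <- video$frames[, r0:r1, c0:c1, drop = FALSE]
  rows <- r0:r1; cols <- c0:c1
  dist2 <- outer((rows - r_c)^2, (cols - roi$x_px)^2, `+`)
  mask <- dist2 <= rad^2
  # Gaussian taper towards the ROI boundary: ROIs of neighbouring cells
  # overlap on crowded epithelia, and a soft window keeps the centre
  # cell's own motion dominant over intruding cilia from neighbours
  wts <- exp(-dist2 / (2 * (rad / 2)^2)) * mask
  list(frames = sub, mask = mask, weights = wts, rows = rows, cols = cols)
}

# internal: separable Gaussian blur with replicated edges
gauss_blur <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  pad <- function(v, n) c(rep(v[1], n), v, rep(v[length(v)], n))
  img <- apply(img, 2, function(col) {
    stats::filter(pad(col, r), k)[(r + 1):(r + h)]
  })
  t(apply(t(img), 2, function(row) {
    stats::filter(pad(row, r), k)[(r + 1):(r + w)]
  }))
}

#' Beat axis of a cell from temporal-difference motion energy
#'
#' Estimates the principal orientation of the moving structure inside a
#' cell's ROI. Consecutive frames are differenced, which isolates the
#' moving cilia from the static background; the per-pixel sum of squared
#' differences over all frame pairs (the motion-energy image) traces the
#' streak each beating cilium sweeps along its beat axis. The amplitude
#' image `sqrt(energy)` is Gaussian-smoothed (gradient estimates on
#' pixel-thin filaments are unreliable without regularization), its
#' spatial gradients are accumulated into a 2 x 2 structure tensor over
#' the ROI, and the beat axis is taken perpendicular to the dominant
#' gradient orientation (gradients of a thin bright streak point across
#' its length). The result is pi-periodic, reported in `[0, pi)` in
#' mathematical convention (counterclockwise from +x, y up).
#'
#' Anisotropy is the normalized eigenvalue contrast of the tensor
#' (`(l1 - l2) / (l1 + l2)`): 0 for isotropic motion, approaching 1 for
#' perfectly linear structure. A static ROI (no temporal change) is
#' flagged absent with `axis_rad = NA` and anisotropy 0.
#'
#' @param video A [video_stack()] with >= 8 frames.
#' @param roi A [cell_roi()].
#' @param smooth_sigma_px Gaussian smoothing scale for the energy image,
#'   in pixels (default 1.5, on the order of the rendered filament
#'   width).
#' @return List with `axis_rad` (`[0, pi)` or `NA`), `anisotropy`,
#'   `energy` (total temporal-difference energy in the ROI).
#' @export
motion_energy_orientation <- function(video, roi, smooth_sigma_px = 1.5) {
  stopifnot(inherits(video, "VideoStack"), inherits(roi, "CellROI"))
  if (dim(video$frames)[1] < 8L) stop("need at least 8 frames")
  cr <- crop_roi(video, roi)
  sub <- cr$frames
  T_ <- dim(sub)[1]; h <- dim(sub)[2]; w <- dim(sub)[3]
  if (h < 3L || w < 3L) stop("ROI too small")
  D <- sub[-1, , , drop = FALSE] - sub[-T_, , , drop = FALSE]
  E <- apply(D * D, c(2, 3), sum)       # motion-energy image (h x w)
  energy <- sum(E[cr$mask])
  if (energy <= 1e-12) {
    return(list(axis_rad = NA_real_, anisotropy = 0, energy = energy))
  }

  A <- gauss_blur(sqrt(E), smooth_sigma_px)
  # central-difference gradients; row index runs down, so gy gets a sign
  # flip to keep y pointing up
  gx <- (A[, c(2:w, w)] - A[, c(1, 1:(w - 1))]) / 2
  gy <- -(A[c(2:h, h), ] - A[c(1, 1:(h - 1)), ]) / 2
  jxx <- sum(gx * gx * cr$weights)
  jyy <- sum(gy * gy * cr$weights)
  jxy <- sum(gx * gy * cr$weights)

  tot <- jxx + jyy
  if (tot <= 1e-12) {
    return(list(axis_rad = NA_real_, anisotropy = 0, energy = energy))
  }
  disc <- sqrt(((jxx - jyy) / 2)^2 + jxy^2)
  anis <- 2 * disc / tot
  grad_or <- 0.5 * atan2(2 * jxy, jxx - jyy)  # dominant gradient orientation
  axis <- wrap_angle(grad_or + pi / 2, pi)    # streak axis is perpendicular
  list(axis_rad = axis, anisotropy = anis, energy = energy)
}

#' Resolve the power-stroke direction along a beat axis
#'
#' A beat axis is a line; the beat *direction* is the half-line the
#' power stroke sweeps along. Two independent signals are combined:
#'
#' *Temporal asymmetry.* The power stroke is the fast phase of the
#' cycle, so it produces larger frame-difference magnitudes than the
#' slow recovery stroke. For every high-motion-energy pixel, the cubed
#' magnitudes of its positive (intensity-rising) and negative (falling)
#' temporal derivatives are summed over time (the cube emphasizes the
#' large, fast transitions that distinguish the strokes and cancels for
#' a time-symmetric beat); the asymmetry score is the median of the
#' per-pixel rise/fall log-ratios, folded to >= 1. The median makes the
#' score robust to the minority of pixels where several desynchronized
#' cilia superpose. A time-symmetric beat gives a ratio of 1 — when the score is
#' below `asymmetry_threshold` the power stroke cannot be identified
#' and the direction is flagged ambiguous (`NA`), the situation in
#' which analysts fall back to axis mode (e.g. for short, damaged
#' cilia).
#'
#' *Distal side.* A beating cilium pivots about its basal body, so
#' motion energy concentrates distally while time-averaged intensity
#' concentrates proximally: the offset from the intensity-weighted to
#' the energy-weighted centroid, projected on the axis, marks the tip
#' side. The power stroke sweeps base-to-tip when intensity rise is the
#' fast transition (ratio > 1) and tip-to-base otherwise.
#'
#' @param video A [video_stack()].
#' @param roi A [cell_roi()].
#' @param axis_rad Axis estimate in radians (e.g. from
#'   [motion_energy_orientation()]); `NA` propagates.
#' @param asymmetry_threshold Minimal rise/fall energy ratio to call a
#'   direction (default 1.2).
#' @param energy_quantile Restrict the temporal statistics to pixels
#'   above this quantile of motion energy inside the ROI (default 0.75),
#'   which keeps background noise from diluting the asymmetry score.
#' @param min_tipward_px Minimal centroid offset (in pixels) along the
#'   axis required to call the tip side (default 0.5). A sub-resolution
#'   offset carries no reliable sign information, so such cells are
#'   flagged ambiguous rather than assigned a coin-flip direction.
#' @return List with `direction_rad` (in `[0, 2*pi)`, reducing mod pi to
#'   `axis_rad`; `NA` when ambiguous or the axis was absent) and
#'   `asymmetry` (the rise/fall ratio folded to >= 1).
#' @export
resolve_direction <- function(video, roi, axis_rad,
                              asymmetry_threshold = 1.2,
                              energy_quantile = 0.75,
                              min_tipward_px = 0.5) {
  stopifnot(inherits(video, "VideoStack"), inherits(roi, "CellROI"))
  if (is.na(axis_rad)) {
    return(list(direction_rad = NA_real_, asymmetry = 1))
  }
  cr <- crop_roi(video, roi)
  sub <- cr$frames
  T_ <- dim(sub)[1]; h <- dim(sub)[2]; w <- dim(sub)[3]
  It <- sub[-1, , , drop = FALSE] - sub[-T_, , , drop = FALSE]
  E <- apply(It * It, c(2, 3), sum)                # motion-energy image
  # noise floor: sensor noise contributes the same expected difference
  # energy everywhere, so the ROI median is subtracted before any
  # energy weighting
  E <- pmax(E - stats::median(E[cr$mask]), 0)
  E <- E * cr$weights
  if (sum(E) <= 1e-12) {
    return(list(direction_rad = NA_real_, asymmetry = 1))
  }

  # high-motion pixels only: both the asymmetry statistic and the
  # centroids should reflect the moving cilia, not the noise floor
  thr <- stats::quantile(E[cr$mask], energy_quantile)
  hot <- E > thr & cr$mask & E > 0
  if (!any(hot)) hot <- cr$mask & E > 0
  if (!any(hot)) hot <- cr$mask

  # per-pixel rise/fall contrast, aggregated by the median log-ratio:
  # a pixel swept by a single cilium rises fast (power stroke) and
  # falls slowly (recovery) or vice versa, and the median over pixels
  # is robust to the minority where several desynchronized cilia
  # superpose
  Itm <- matrix(aperm(It, c(2, 3, 1)), ncol = T_ - 1)  # pixels x pairs
  # sensor-noise floor of the temporal derivative, from the robust MAD
  # over the whole ROI (mostly background); derivatives below 3 sigma
  # are noise, not stroke transitions, and would dilute the ratio
  # toward 1
  sigma_it <- 1.4826 * stats::median(abs(Itm[as.vector(cr$mask), ]))
  Ith <- Itm[as.vector(hot), , drop = FALSE]
  Ith[abs(Ith) < 3 * sigma_it] <- 0
  rise_p <- rowSums(pmax(Ith, 0)^3)
  fall_p <- rowSums(pmax(-Ith, 0)^3)
  use <- rise_p > 0 & fall_p > 0
  if (sum(use) < 4L) {
    return(list(direction_rad = NA_real_, asymmetry = 1))
  }
  med_log <- stats::median(log(rise_p[use] / fall_p[use]))
  ratio <- exp(med_log)
  score <- max(ratio, 1 / ratio)
  if (!is.finite(score) || score < asymmetry_threshold) {
    return(list(direction_rad = NA_real_, asymmetry = ifelse(is.finite(score), score, 1)))
  }

  # tip side: energy centroid minus intensity centroid, projected on u
  M <- apply(sub, c(2, 3), mean)
  M <- pmax(M - stats::median(M[cr$mask]), 0)      # remove flat background
  M <- M * cr$weights
  xs <- cr$cols
  ys <- dim(video$frames)[2] + 1 - cr$rows          # math y of each row
  xg <- matrix(xs, h, w, byrow = TRUE)
  yg <- matrix(ys, h, w)
  if (sum(M) <= 1e-12) {
    return(list(direction_rad = NA_real_, asymmetry = score))
  }
  ce <- c(sum(E * xg), sum(E * yg)) / sum(E)
  cm <- c(sum(M * xg), sum(M * yg)) / sum(M)
  u <- c(cos(axis_rad), sin(axis_rad))
  tipward <- sum((ce - cm) * u)
  if (abs(tipward) < min_tipward_px) {
    return(list(direction_rad = NA_real_, asymmetry = score))
  }
  # rise-dominant: power stroke is the fast extension toward the tip;
  # fall-dominant: the fast stroke runs tip-to-base
  dir_sign <- sign(tipward) * (if (ratio >= 1) 1 else -1)
  dir <- if (dir_sign > 0) axis_rad else axis_rad + pi
  list(direction_rad = wrap_angle(dir, 2 * pi), asymmetry = score)
}

#' Estimate beat angles for a set of cells
#'
#' Runs [motion_energy_orientation()] (and, in direction mode,
#' [resolve_direction()]) over a list of ROIs and collects the results
#' into an [angle_set()] with `source = "estimated"`. Cells whose axis is
#' absent (static ROI) or whose direction is ambiguous are dropped from
#' the set and reported in the `flagged` attribute; a warning summarizes
#' them.
#'
#' @param video A [video_stack()].
#' @param rois List of [cell_roi()] objects.
#' @param mode `"direction"` or `"axis"`.
#' @param asymmetry_threshold Passed to [resolve_direction()].
#' @param warn_small Passed to [angle_set()].
#' @return An [angle_set()] with attributes `flagged` (data frame of
#'   dropped cells and reasons) and `details` (per-cell data frame with
#'   axis, anisotropy, asymmetry).
#' @export
estimate_angles <- function(video, rois, mode = c("direction", "axis"),
                            asymmetry_threshold = 1.2, warn_small = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(rois) >= 1L)
  res <- lapply(rois, function(roi) {
    ax <- motion_energy_orientation(video, roi)
    out <- list(cell_id = roi$cell_id, axis_rad = ax$axis_rad,
                anisotropy = ax$anisotropy, asymmetry = NA_real_,
                angle_rad = ax$axis_rad, reason = NA_character_)
    if (is.na(ax$axis_rad)) {
      out$reason <- "static ROI: no motion energy"
      return(out)
    }
    if (mode == "direction") {
      dr <- resolve_direction(video, roi, ax$axis_rad, asymmetry_threshold)
      out$asymmetry <- dr$asymmetry
      out$angle_rad <- dr$direction_rad
      if (is.na(dr$direction_rad)) {
        out$reason <- "ambiguous power-stroke direction"
      }
    }
    out
  })
  details <- do.call(rbind, lapply(res, function(r) {
    data.frame(cell_id = r$cell_id, axis_rad = r$axis_rad,
               anisotropy = r$anisotropy, asymmetry = r$asymmetry,
               angle_rad = r$angle_rad, reason = r$reason,
               stringsAsFactors = FALSE)
  }))
  keep <- !is.na(details$angle_rad)
  flagged <- details[!keep, c("cell_id", "reason")]
  if (nrow(flagged) > 0L) {
    warning(sprintf("%d of %d cells flagged (%s)", nrow(flagged),
                    length(rois),
                    paste(unique(flagged$reason), collapse = "; ")),
            call. = FALSE)
  }
  if (!any(keep)) stop("no cell yielded a usable angle")
  out <- angle_set(details$angle_rad[keep], mode = mode,
                   cell_ids = details$cell_id[keep], source = "estimated",
                   warn_small = warn_small)
  attr(out, "flagged") <- flagged
  attr(out, "details") <- details
  out
}

#' Load manual per-cell angle annotations
#'
#' Ingests a CSV of manually measured beat angles (one row per ciliated
#' cell, angles in degrees, as produced by measuring each cell in an
#' image-analysis tool). Angles are converted to radians and reduced to
#' the mode's fundamental domain: `[0, 360)` degrees for directions,
#' `[0, 180)` for axes (with a warning when axis-mode input spans more
#' than 180 degrees, since the arrowhead information is discarded).
#'
#' @param path CSV file with (at least) columns `cell_id`, `angle_deg`.
#' @param mode `"direction"` or `"axis"`.
#' @param warn_small Passed to [angle_set()] (fewer than 15 cells warns).
#' @return An [angle_set()] with `source = "manual"`.
#' @export
load_manual_angles <- function(path, mode = c("direction", "axis"),
                               warn_small = TRUE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "angle_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")))
  }
  ang <- df$angle_deg
  if (!is.numeric(ang) || anyNA(suppressWarnings(as.numeric(ang)))) {
    stop("`angle_deg` must be numeric and free of missing values")
  }
  check_finite(ang, "angle_deg")
  if (mode == "axis") {
    span <- wrap_angle(deg2rad(ang), 2 * pi)
    if (any(span >= pi)) {
      warning("axis-mode angles span more than 180 degrees; reducing modulo 180",
              call. = FALSE)
    }
  }
  angle_set(deg2rad(ang), mode = mode, cell_ids = df$cell_id,
            source = "manual", warn_small = warn_small)
}

#' Read cell ROIs from a CSV table
#'
#' @param path CSV with columns `cell_id`, `x_px`, `y_px` and optionally
#'   `radius_px`.
#' @param radius_px Default radius when the file has no `radius_px`
#'   column.
#' @return List of [cell_roi()] objects.
#' @export
load_rois <- function(path, radius_px = 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x_px", "y_px")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")))
  }
  rad <- if ("radius_px" %in% names(df)) df$radius_px else rep(radius_px, nrow(df))
  lapply(seq_len(nrow(df)), function(i) {
    cell_roi(df$cell_id[i], df$x_px[i], df$y_px[i], rad[i])
  })
}
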