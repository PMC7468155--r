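#' Convert degrees to radians
#'
#' @param deg Angle(s) in degrees.
#' @return Angle(s) in radians.
#' @export
deg2rad <- function(deg) deg * pi / 180

#' Convert radians to degrees
#'
#' @param rad Angle(s) in radians.
#' @return Angle(s) in degrees.
#' @export
rad2deg <- function(rad) rad * 180 / pi

#' Reduce angles to a fundamental domain
#'
#' Wraps angles into `[0, period)`. Used with `period = 2*pi` for
#' directional (2pi-periodic) data and `period = pi` for axial
#' (pi-periodic) data.
#'
#' @param x Numeric angles in radians.
#' @param period Positive period, typically `2*pi` or `pi`.
#' @return Angles wrapped into `[0, period)`.
#' @export
wrap_angle <- function(x, period = 2 * pi) {
  stopifnot(is.numeric(x), period > 0)
  out <- x %% period
  # roundoff can leave values within one ulp of `period` (e.g. the
  # circular mean of angles straddling zero); those are the same angle
  # as 0
  out[out >= period * (1 - 4 * .Machine$double.eps)] <- 0
  out
}

# internal: stop unless all values are finite numbers
check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric, got non-finite values", what),
         call. = FALSE)
  }
  invisible(x)
}
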