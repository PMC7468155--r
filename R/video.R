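#' Construct a video stack
#'
#' A `VideoStack` is a T x H x W array of non-negative intensities plus
#' the acquisition frame rate — the raw observable of high-speed
#' recordings of beating cilia (typically captured at 50 or 125 fps).
#'
#' @param frames Numeric T x H x W array, T >= 2, all finite.
#' @param frame_rate_fps Acquisition rate in frames per second (> 0).
#' @param pixel_size_um Optional pixel size in um/px.
#' @return An object of class `VideoStack`.
#' @export
video_stack <- function(frames, frame_rate_fps, pixel_size_um = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a T x H x W array")
  }
  if (dim(frames)[1] < 2L) stop("a video needs at least 2 frames (T >= 2)")
  if (anyNA(frames) || any(!is.finite(frames))) {
    stop("all frame intensities must be finite")
  }
  stopifnot(is.numeric(frame_rate_fps), length(frame_rate_fps) == 1L,
            frame_rate_fps > 0)
  if (!is.null(pixel_size_um)) stopifnot(pixel_size_um > 0)
  structure(list(frames = frames, frame_rate_fps = frame_rate_fps,
                 pixel_size_um = pixel_size_um),
            class = "VideoStack")
}

#' @export
print.VideoStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("VideoStack: %d frames of %d x %d px @ %g fps (%.2f s)\n",
              d[1], d[2], d[3], x$frame_rate_fps, d[1] / x$frame_rate_fps))
  invisible(x)
}

# sidecar metadata path for a TIFF stack
sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a video stack as a multi-page 16-bit TIFF
#'
#' Intensities are rounded to integers and clamped to the 16-bit range.
#' The frame rate (and pixel size, if known) is recorded in a sidecar
#' JSON metadata file next to the TIFF, since this is what
#' [read_stack()] reads back. Writing then reading returns a
#' pixel-identical stack.
#'
#' @param video A [video_stack()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(video, path) {
  stopifnot(inherits(video, "VideoStack"))
  d <- dim(video$frames)
  q <- round(video$frames)
  q[q < 0] <- 0
  q[q > 65535] <- 65535
  pages <- lapply(seq_len(d[1]), function(t) q[t, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  meta <- list(frame_rate_fps = video$frame_rate_fps,
               pixel_size_um = video$pixel_size_um,
               n_frames = d[1], height_px = d[2], width_px = d[3],
               bit_depth = 16L)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF video stack
#'
#' Accepts 8/16-bit integer and float grayscale TIFFs with uniform page
#' shape. The frame rate is taken from the sidecar JSON metadata file
#' (written by [write_stack()]) or, failing that, from the
#' `frame_rate_fps` argument; an error names the argument when neither
#' is available.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param frame_rate_fps Frame rate override/fallback in fps.
#' @param pixel_size_um Optional pixel size override in um/px.
#' @return A [video_stack()]. Integer inputs are returned on their
#'   native intensity scale (e.g. 0..65535 for 16-bit).
#' @export
read_stack <- function(path, frame_rate_fps = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    stop("a video needs at least 2 frames (T >= 2); got a single-page TIFF")
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # drop extra channels
    p
  })
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("ragged TIFF: all pages must have the same dimensions")
  }
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  fps <- frame_rate_fps
  if (is.null(fps) && !is.null(meta$frame_rate_fps)) fps <- meta$frame_rate_fps
  if (is.null(fps)) {
    stop(sprintf(
      "frame rate not found for '%s': no sidecar '%s'; supply `frame_rate_fps`",
      path, sp))
  }
  px <- pixel_size_um
  if (is.null(px) && !is.null(meta$pixel_size_um) &&
      !is.na(meta$pixel_size_um)) {
    px <- meta$pixel_size_um
  }
  H <- dims[1, 1]; W <- dims[2, 1]
  frames <- array(0, dim = c(length(pages), H, W))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
  video_stack(frames, frame_rate_fps = fps, pixel_size_um = px)
}
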