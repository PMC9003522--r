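#' RGB video frame stack
#'
#' Container for a time-ordered stack of 8-bit RGB frames together with the
#' acquisition metadata the downstream analysis needs: the frame rate and the
#' physical extent of one pixel.
#'
#' @param frames 4-D numeric array indexed \code{(t, row, col, channel)} with
#'   values in \code{[0, 255]} and exactly 3 channels. A list of
#'   \code{height x width x 3} arrays is also accepted and bound along time.
#' @param fps frames per second (Hz), \code{> 0}.
#' @param pixel_pitch physical length covered by one pixel, in the scale unit
#'   used for kernel-extent reporting (default 0.08 per pixel, the
#'   acquisition geometry assumed throughout; see \code{\link{kernel_extent}}).
#' @param subject_id free-text identifier carried through to outputs.
#' @param meta named list of additional metadata.
#'
#' @return An object of class \code{frame_stack}: a list with elements
#'   \code{frames}, \code{fps}, \code{pixel_pitch}, \code{subject_id},
#'   \code{meta}.
#'
#' @examples
#' fs <- frame_stack(array(0L, c(2, 4, 4, 3)), fps = 40)
#' dim(fs$frames)
#' @export
frame_stack <- function(frames, fps, pixel_pitch = 0.08,
                        subject_id = NA_character_, meta = list()) {
  if (is.list(frames)) {
    d <- lapply(frames, dim)
    if (length(frames) == 0L) stop("frame stack must contain at least one frame")
    if (!all(vapply(d, length, 1L) == 3L) ||
        length(unique(vapply(d, paste, "", collapse = "x"))) != 1L) {
      stop("inconsistent frame geometry: all frames must share height x width x 3")
    }
    a <- array(0, c(length(frames), d[[1]]))
    for (t in seq_along(frames)) a[t, , , ] <- frames[[t]]
    frames <- a
  }
  x <- structure(list(frames = frames, fps = fps, pixel_pitch = pixel_pitch,
                      subject_id = subject_id, meta = meta),
                 class = "frame_stack")
  validate_frame_stack(x)
}

#' Validate a frame stack against its invariants
#'
#' Checks dimensionality, the 3-channel constraint, the 8-bit value range and
#' positivity of \code{fps} and \code{pixel_pitch}.
#'
#' @param x a \code{frame_stack}.
#' @return \code{x}, invisibly-checked (returned unchanged on success).
#' @export
validate_frame_stack <- function(x) {
  f <- x$frames
  if (!is.array(f) || length(dim(f)) != 4L)
    stop("frames must be a 4-D (t, row, col, channel) array")
  d <- dim(f)
  if (d[1] < 1L) stop("frame stack must contain at least one frame")
  if (d[4] != 3L) stop("frame stack must have exactly 3 color channels")
  rng <- range(f)
  if (rng[1] < 0 || rng[2] > 255)
    stop("pixel values must lie in [0, 255]")
  if (!is.numeric(x$fps) || length(x$fps) != 1L || x$fps <= 0)
    stop("fps must be a single positive number")
  if (!is.numeric(x$pixel_pitch) || x$pixel_pitch <= 0)
    stop("pixel_pitch must be positive")
  x
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d RGB @ %g fps (pixel pitch %g)\n",
              d[1], d[2], d[3], x$fps, x$pixel_pitch))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Single-channel scalar stack
#'
#' A time-ordered stack of single-channel frames, produced by
#' \code{\link{to_channel}} (luminance, hue or saturation) or by band-pass
#' filtering. Values carry the units of the channel: luminance in
#' \code{[0, 255]}, saturation in \code{[0, 1]}, hue in degrees
#' \code{[0, 360)}.
#'
#' @param values 3-D numeric array indexed \code{(t, row, col)}.
#' @param channel_kind one of \code{"luminance"}, \code{"hue"},
#'   \code{"saturation"}.
#' @param fps frames per second (Hz).
#' @param pixel_pitch physical length per pixel.
#' @return An object of class \code{scalar_stack}.
#' @export
scalar_stack <- function(values, channel_kind, fps, pixel_pitch = 0.08) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D (t, row, col) array")
  channel_kind <- match.arg(channel_kind, c("luminance", "hue", "saturation"))
  if (fps <= 0) stop("fps must be positive")
  structure(list(values = values, channel_kind = channel_kind, fps = fps,
                 pixel_pitch = pixel_pitch),
            class = "scalar_stack")
}

#' @export
print.scalar_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<scalar_stack:%s> %d frames of %d x %d @ %g fps\n",
              x$channel_kind, d[1], d[2], d[3], x$fps))
  invisible(x)
}

#' One pixel's time series
#'
#' @param samples numeric vector of channel values over time.
#' @param fps sampling rate (Hz).
#' @param origin \code{(row, col)} of the trace in source coordinates.
#' @param kernel_size moving-average kernel size N used to produce it
#'   (1 = unfiltered pixel).
#' @return An object of class \code{pixel_trace}.
#' @export
pixel_trace <- function(samples, fps, origin = c(NA, NA), kernel_size = 1L) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("trace must be a non-empty numeric vector")
  structure(list(samples = as.numeric(samples), fps = fps,
                 origin = origin, kernel_size = kernel_size),
            class = "pixel_trace")
}

# Resolve (samples, fps) from a pixel_trace or a bare numeric vector.
.trace_samples <- function(x, fps = NULL) {
  if (inherits(x, "pixel_trace")) return(list(samples = x$samples, fps = x$fps))
  if (is.numeric(x)) {
    if (is.null(fps)) stop("fps must be supplied for a bare numeric trace")
    return(list(samples = as.numeric(x), fps = fps))
  }
  stop("expected a pixel_trace or numeric vector")
}

#' Extract a (kernel-averaged) pixel trace from a stack
#'
#' Returns the time series of the uniform \code{kernel_size x kernel_size}
#' neighborhood mean centered on \code{roi}, which for the uniform kernel is
#' identical to filtering every frame with \code{\link{moving_average}} and
#' reading the filtered pixel at \code{roi}.
#'
#' @param stack a \code{scalar_stack}.
#' @param roi integer \code{c(row, col)}, 1-based, in source coordinates.
#' @param kernel_size odd kernel size N (default 1: the raw pixel).
#' @return A \code{\link{pixel_trace}}.
#' @export
extract_trace <- function(stack, roi, kernel_size = 1L) {
  stopifnot(inherits(stack, "scalar_stack"))
  d <- dim(stack$values)
  k <- .check_roi(roi, kernel_size, d[2], d[3])
  if (kernel_size == 1L) {
    s <- stack$values[, roi[1], roi[2]]
  } else {
    z <- .integral_stack(stack$values)
    s <- .window_mean(z, roi[1], roi[2], k)
  }
  pixel_trace(s, stack$fps, origin = roi, kernel_size = kernel_size)
}

.check_roi <- function(roi, n, h, w) {
  if (length(roi) != 2L || any(roi < 1) || roi[1] > h || roi[2] > w)
    stop("roi must be a (row, col) pair inside the frame")
  if (n %% 2 == 0L || n < 1L) stop("kernel size must be odd and >= 1")
  k <- (n - 1L) / 2L
  if (roi[1] - k < 1 || roi[1] + k > h || roi[2] - k < 1 || roi[2] + k > w)
    stop("roi outside the valid region for kernel size ", n)
  k
}
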