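# Channel conversion.
#
# The pulse wave can in principle be read from luminance, hue or saturation
# variation; in practice luminance gives the largest peak-to-peak swing with
# the least superimposed noise, so the quantification pipeline runs on
# luminance. Hue and saturation conversions are provided for the comparison.

#' Convert an RGB stack to a single-channel stack
#'
#' Luminance is a fixed weighted RGB sum (ITU-style weights
#' 0.299 R + 0.587 G + 0.114 B by default, configurable -- e.g.
#' \code{c(0, 0, 1)} for a blue-channel-only readout matching a blue
#' illuminator). Hue and saturation use the standard hexcone (HSV) model:
#' hue in degrees [0, 360), saturation in [0, 1]. Hue of achromatic pixels
#' (R = G = B), mathematically undefined, is set to 0 and flagged in the
#' \code{"achromatic"} attribute so NaNs never reach the FFT stage.
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param channel_kind \code{"luminance"}, \code{"hue"} or
#'   \code{"saturation"}.
#' @param luma_weights length-3 non-negative weights for the luminance sum;
#'   normalized internally to sum to 1.
#' @return A \code{\link{scalar_stack}} of the same (t, row, col) shape.
#' @examples
#' fs <- frame_stack(array(255L, c(1, 2, 2, 3)), fps = 40)
#' max(to_channel(fs, "luminance")$values)  # 255
#' @export
to_channel <- function(stack, channel_kind = c("luminance", "hue", "saturation"),
                       luma_weights = c(0.299, 0.587, 0.114)) {
  channel_kind <- match.arg(channel_kind)
  validate_frame_stack(stack)
  f <- stack$frames
  d <- dim(f)
  if (channel_kind == "luminance") {
    if (length(luma_weights) != 3L || any(luma_weights < 0) ||
        sum(luma_weights) == 0)
      stop("luma_weights must be 3 non-negative values with positive sum")
    w <- luma_weights / sum(luma_weights)
    v <- w[1] * f[, , , 1] + w[2] * f[, , , 2] + w[3] * f[, , , 3]
    dim(v) <- d[1:3]
  } else {
    rgbm <- rbind(as.vector(f[, , , 1]), as.vector(f[, , , 2]),
                  as.vector(f[, , , 3]))
    hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 255)
    v <- if (channel_kind == "hue") (hsv[1, ] * 360) %% 360 else hsv[2, ]
    dim(v) <- d[1:3]
    out <- scalar_stack(v, channel_kind, stack$fps, stack$pixel_pitch)
    attr(out, "achromatic") <- array(f[, , , 1] == f[, , , 2] &
                                       f[, , , 2] == f[, , , 3], d[1:3])
    return(out)
  }
  scalar_stack(v, channel_kind, stack$fps, stack$pixel_pitch)
}

#' Peak-to-peak value of a trace
#'
#' The waveform's max minus min, in the units of the trace. Used to compare
#' pulse-wave visibility across channels (luminance vs. hue vs. saturation).
#'
#' @param trace a \code{\link{pixel_trace}} or numeric vector.
#' @return A single number, \code{max - min}.
#' @examples
#' peak_to_peak(sin(seq(0, 2 * pi, length.out = 100)))  # close to 2
#' @export
peak_to_peak <- function(trace) {
  s <- if (inherits(trace, "pixel_trace")) trace$samples else trace
  if (!is.numeric(s) || length(s) == 0L) stop("trace must be non-empty")
  diff(range(s))
}
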