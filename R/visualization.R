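# Hemodynamic color-map visualization.
#
# Band-passed luminance change is quantized to 256 color levels and rendered
# frame by frame. With the default diverging palette, the blue end marks
# positive luminance change (the tense, distended anastomosis reflecting
# more light toward the camera) and the red end negative change; zero change
# sits at the palette center.

#' Build a 256-level color map
#'
#' Quantizes the domain \code{[vmin, vmax]} linearly into 256 levels
#' (left-closed bins: level = \code{floor(256 * (v - vmin) / (vmax - vmin))}
#' clamped to 0..255, so the exact midpoint lands on level 128 and
#' out-of-domain values clamp to the end levels). All 256 colors are
#' guaranteed distinct and the level index is monotone in the input.
#'
#' @param palette \code{"blue-red"} (default: diverging, red at \code{vmin},
#'   blue at \code{vmax} -- the tense end), \code{"red-blue"} (reversed), or
#'   \code{"grey"}.
#' @param vmin,vmax domain bounds in luminance-change units,
#'   \code{vmin < vmax}.
#' @return An object of class \code{colormap256}: list with \code{colors}
#'   (256 hex strings), \code{vmin}, \code{vmax}, \code{palette}.
#' @examples
#' cm <- build_colormap("blue-red", -1, 1)
#' length(unique(cm$colors))  # 256
#' @export
build_colormap <- function(palette = c("blue-red", "red-blue", "grey"),
                           vmin = -1, vmax = 1) {
  palette <- match.arg(palette)
  if (!is.finite(vmin) || !is.finite(vmax) || vmin >= vmax)
    stop("vmin must be strictly less than vmax")
  cols <- switch(palette,
    "blue-red" = .diverging_256(c(178, 24, 43), c(33, 102, 172)),
    "red-blue" = rev(.diverging_256(c(178, 24, 43), c(33, 102, 172))),
    "grey" = grDevices::rgb(0:255, 0:255, 0:255, maxColorValue = 255))
  if (length(unique(cols)) != 256L)
    stop("internal error: palette has duplicate levels")
  structure(list(colors = cols, vmin = vmin, vmax = vmax, palette = palette),
            class = "colormap256")
}

# Diverging ramp low -> near-white -> high with 256 guaranteed-distinct
# colors: each half interpolates over 128 steps toward (or away from)
# white (247, 247, 247) without ever reaching it, so at least one channel
# moves by >= 1 per level.
.diverging_256 <- function(low, high) {
  w <- c(247, 247, 247)
  t1 <- (0:127) / 128
  t2 <- (128:1) / 128
  half1 <- outer(t1, w - low) + rep(low, each = 128)
  half2 <- outer(t2, w - high) + rep(high, each = 128)
  m <- round(rbind(half1, half2))
  grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
}

#' Map values to color levels
#'
#' @param values numeric vector or array.
#' @param cmap a \code{\link{build_colormap}} object.
#' @return Integer level indices 0..255 with the shape of \code{values}.
#' @export
map_to_levels <- function(values, cmap) {
  stopifnot(inherits(cmap, "colormap256"))
  t <- (values - cmap$vmin) / (cmap$vmax - cmap$vmin)
  lvl <- pmin(pmax(floor(t * 256), 0), 255)
  storage.mode(lvl) <- "integer"
  lvl
}

#' Render a band-passed stack as color-mapped RGB frames
#'
#' Every frame is quantized with one fixed color map, so identical luminance
#' changes map to identical colors throughout the sequence and frames are
#' directly comparable. When no map is supplied, the domain defaults to the
#' sequence-global symmetric range \code{[-max|v|, +max|v|]} computed over
#' the whole stack, keeping zero change at the palette center.
#'
#' @param stack a \code{\link{scalar_stack}} of band-passed luminance change
#'   (see \code{\link{band_pass_stack}}).
#' @param cmap optional \code{\link{build_colormap}} object.
#' @param t_range integer frame indices to render (default: all frames).
#' @return An integer array \code{(t, row, col, 3)} of 8-bit RGB values with
#'   the color map attached as attribute \code{"cmap"}.
#' @export
render_sequence <- function(stack, cmap = NULL, t_range = NULL) {
  stopifnot(inherits(stack, "scalar_stack"))
  d <- dim(stack$values)
  if (is.null(t_range)) t_range <- seq_len(d[1])
  if (length(t_range) == 0L) stop("t_range must select at least one frame")
  if (any(t_range < 1 | t_range > d[1])) stop("t_range outside the recording")
  if (is.null(cmap)) {
    m <- max(abs(stack$values))
    if (m == 0) m <- 1  # all-zero stack: degenerate, map everything mid-level
    cmap <- build_colormap("blue-red", -m, m)
  }
  v <- stack$values[t_range, , , drop = FALSE]
  lvl <- map_to_levels(v, cmap)
  rgbm <- grDevices::col2rgb(cmap$colors)  # 3 x 256
  out <- array(0L, c(dim(v), 3L))
  for (ch in 1:3) out[, , , ch] <- rgbm[ch, lvl + 1L]
  attr(out, "cmap") <- cmap
  out
}

#' Write rendered frames as PNG files
#'
#' @param frames array returned by \code{\link{render_sequence}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (files are \code{prefix_0001.png}, ...).
#' @return Invisibly, the written paths.
#' @export
write_frames_png <- function(frames, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- dim(frames)[1]
  paths <- file.path(dir, sprintf("%s_%04d.png", prefix, seq_len(nt)))
  for (t in seq_len(nt)) {
    img <- frames[t, , , , drop = TRUE] / 255
    png::writePNG(img, paths[t])
  }
  invisible(paths)
}
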