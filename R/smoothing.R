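# Spatial moving-average filtering.
#
# The filter convolves each frame with an N x M kernel of weights h(m, n),
# sliding one pixel at a time in a raster scan; with the default uniform
# weights 1/(N*M) the output pixel is the plain neighborhood mean. Because
# every pixel carries the same in-phase pulse while sensor noise is
# independent across pixels, enlarging the kernel acts like additive
# averaging: the pulse survives, the noise variance drops as 1/(N*M).

#' Uniform moving-average kernel
#'
#' @param n odd kernel height (pixels).
#' @param m odd kernel width (defaults to \code{n} for a square kernel).
#' @return An \code{n x m} matrix of weights summing to 1.
#' @examples
#' uniform_kernel(3)
#' @export
uniform_kernel <- function(n, m = n) {
  .check_odd(n, "n"); .check_odd(m, "m")
  matrix(1 / (n * m), n, m)
}

.check_odd <- function(x, what) {
  if (length(x) != 1L || x < 1L || x %% 2 == 0L)
    stop(sprintf("%s must be an odd positive integer, got %s", what, x))
}

#' Spatial moving-average filter
#'
#' Filters every frame of a stack (or a single matrix) with a centered
#' \code{N x M} kernel. Only fully-interior pixels are produced by default
#' ("valid" convention): the output frame is \code{(H - N + 1) x (W - M + 1)}
#' and its origin sits at source pixel \code{((N+1)/2, (M+1)/2)}. A
#' reflect-padding mode producing full-size frames is available but off by
#' default, since padded borders bias band-power estimates.
#'
#' @param x a \code{scalar_stack} or a numeric matrix (one frame).
#' @param kernel either a single odd integer N (uniform \code{N x N} kernel)
#'   or a weight matrix with odd dimensions (see \code{\link{uniform_kernel}};
#'   arbitrary weights are accepted).
#' @param pad \code{"valid"} (default) or \code{"reflect"}.
#' @return For a matrix input, the filtered matrix. For a stack, an object of
#'   class \code{smoothed_stack} with elements \code{values} (t, row, col over
#'   the valid region), \code{kernel_size} \code{c(N, M)},
#'   \code{origin_offset} (row/col of the valid-region origin in source
#'   coordinates), \code{fps}.
#' @examples
#' moving_average(matrix(1:9, 3, byrow = TRUE), 3)  # single value: 5
#' @export
moving_average <- function(x, kernel, pad = c("valid", "reflect")) {
  pad <- match.arg(pad)
  if (is.matrix(kernel)) {
    w <- kernel
  } else {
    .check_odd(kernel, "kernel size")
    w <- NULL  # uniform fast path
    kernel <- as.integer(kernel)
  }
  n <- if (is.null(w)) kernel else nrow(w)
  m <- if (is.null(w)) kernel else ncol(w)
  if (!is.null(w)) { .check_odd(n, "kernel rows"); .check_odd(m, "kernel cols") }

  if (is.matrix(x)) {
    a <- array(x, c(1L, dim(x)))
    out <- .ma_core(a, n, m, w, pad)
    return(matrix(out, dim(out)[2], dim(out)[3]))
  }
  stopifnot(inherits(x, "scalar_stack"))
  v <- .ma_core(x$values, n, m, w, pad)
  structure(list(values = v, kernel_size = c(n, m),
                 origin_offset = if (pad == "valid")
                   c((n + 1L) %/% 2L, (m + 1L) %/% 2L) else c(1L, 1L),
                 fps = x$fps, channel_kind = x$channel_kind,
                 pixel_pitch = x$pixel_pitch),
            class = c("smoothed_stack", "scalar_stack"))
}

.ma_core <- function(a, n, m, w, pad) {
  d <- dim(a); h <- d[2]; wd <- d[3]
  if (n > h || m > wd) stop("kernel larger than frame (", n, "x", m,
                            " vs ", h, "x", wd, ")")
  if (pad == "reflect") {
    kr <- (n - 1L) / 2L; kc <- (m - 1L) / 2L
    ri <- c(rev(seq_len(kr) + 1L), seq_len(h), h - seq_len(kr))
    ci <- c(rev(seq_len(kc) + 1L), seq_len(wd), wd - seq_len(kc))
    a <- a[, ri, ci, drop = FALSE]
    h <- dim(a)[2]; wd <- dim(a)[3]
  }
  hv <- h - n + 1L; wv <- wd - m + 1L
  if (is.null(w)) {
    z <- .integral_stack(a)
    r0 <- seq_len(hv); c0 <- seq_len(wv)
    g <- z[, r0 + n, c0 + m, drop = FALSE] - z[, r0, c0 + m, drop = FALSE] -
      z[, r0 + n, c0, drop = FALSE] + z[, r0, c0, drop = FALSE]
    g / (n * m)
  } else {
    g <- array(0, c(d[1], hv, wv))
    for (i in seq_len(n)) for (j in seq_len(m)) {
      if (w[i, j] == 0) next
      g <- g + w[i, j] * a[, (i - 1L) + seq_len(hv), (j - 1L) + seq_len(wv), drop = FALSE]
    }
    g
  }
}

# Zero-padded 2-D running sums per frame: z has dim (t, H+1, W+1) and the
# window sum over rows r1..r2, cols c1..c2 of frame t is
# z[t, r2+1, c2+1] - z[t, r1, c2+1] - z[t, r2+1, c1] + z[t, r1, c1].
.integral_stack <- function(a) {
  s <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))  # cumsum down rows
  s <- aperm(apply(s, c(1, 2), cumsum), c(2, 3, 1))  # then across cols
  d <- dim(a)
  z <- array(0, d + c(0L, 1L, 1L))
  z[, -1L, -1L] <- s
  z
}

# Mean of the (2k+1)^2 window centered at (r, c), all frames at once.
.window_mean <- function(z, r, c, k) {
  n <- 2L * k + 1L
  (z[, r + k + 1L, c + k + 1L] - z[, r - k, c + k + 1L] -
     z[, r + k + 1L, c - k] + z[, r - k, c - k]) / (n * n)
}

#' Kernel sizes for the SNR sweep
#'
#' The standard sweep runs square kernels from 1x1 to 201x201 in steps of
#' 2 pixels (odd sizes only, so every kernel has a center pixel).
#'
#' @param n_min,n_max odd inclusive bounds (defaults 1 and 201).
#' @param step increment (default 2).
#' @return Integer vector of odd kernel sizes.
#' @examples
#' length(kernel_sweep_sizes())  # 101
#' @export
kernel_sweep_sizes <- function(n_min = 1L, n_max = 201L, step = 2L) {
  .check_odd(n_min, "n_min"); .check_odd(n_max, "n_max")
  if (n_min > n_max) stop("n_min must not exceed n_max")
  as.integer(seq(n_min, n_max, by = step))
}

#' Physical extent of a kernel
#'
#' Converts a kernel size in pixels to physical units using the pixel pitch
#' (default 0.08 per pixel, so a 201-pixel kernel spans 16.08).
#'
#' @param n kernel size in pixels.
#' @param pixel_pitch physical length per pixel.
#' @return \code{n * pixel_pitch}.
#' @export
kernel_extent <- function(n, pixel_pitch = 0.08) n * pixel_pitch
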