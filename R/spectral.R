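# FFT band decomposition and the SNAVF statistic.
#
# The pulse-wave band is 1-5 Hz (resting heart rates of 60-100 bpm plus the
# second harmonic); the noise band is 10-19 Hz, above the 5-10 Hz thrill
# band so thrill energy cannot contaminate the noise estimate, and below the
# 20 Hz Nyquist limit at 40 fps. Each band-pass filter is realized by a
# 256-point FFT mask. The statistic is
#
#   SNAVF = max over kernel sizes N of AVFs(N) / AVFn(N)
#
# where AVFs is the power at the in-band fundamental plus its second
# harmonic, and AVFn is the sum of the two largest bin powers in 10-19 Hz.

#' Band and FFT configuration
#'
#' @param signal_band pulse-wave band in Hz (default \code{c(1, 5)}).
#' @param noise_band noise band in Hz (default \code{c(10, 19)}).
#' @param fft_size FFT sample size (default 256); traces are analyzed on
#'   their first \code{fft_size} samples.
#' @param n_noise_peaks number of largest noise-band components summed into
#'   AVFn (default 2).
#' @param window \code{"rect"} (default; keeps on-grid tones exact) or
#'   \code{"hann"} for leakage suppression on off-grid data.
#' @return A list of class \code{band_config}.
#' @export
band_config <- function(signal_band = c(1, 5), noise_band = c(10, 19),
                        fft_size = 256L, n_noise_peaks = 2L,
                        window = c("rect", "hann")) {
  window <- match.arg(window)
  if (length(signal_band) != 2L || length(noise_band) != 2L ||
      signal_band[1] >= signal_band[2] || noise_band[1] >= noise_band[2])
    stop("bands must be increasing (lo, hi) pairs")
  if (signal_band[2] >= noise_band[1] && noise_band[2] >= signal_band[1])
    if (max(signal_band[1], noise_band[1]) <= min(signal_band[2], noise_band[2]))
      stop("signal and noise bands must be disjoint")
  if (signal_band[1] <= 0) stop("bands must lie within (0, fps/2]")
  structure(list(signal_band = signal_band, noise_band = noise_band,
                 fft_size = as.integer(fft_size),
                 n_noise_peaks = as.integer(n_noise_peaks), window = window),
            class = "band_config")
}

.check_band_nyquist <- function(band, fps) {
  if (band[2] > fps / 2 + 1e-12)
    stop("band upper edge ", band[2], " Hz exceeds Nyquist (", fps / 2, " Hz)")
}

.segment <- function(x, fps, cfg, demean = TRUE) {
  tr <- .trace_samples(x, fps)
  n <- cfg$fft_size
  if (length(tr$samples) < n)
    stop("trace too short: need at least ", n, " samples, got ",
         length(tr$samples))
  s <- tr$samples[seq_len(n)]
  if (demean) s <- s - mean(s)
  if (cfg$window == "hann")
    s <- s * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n))
  list(s = s, fps = tr$fps)
}

#' One-sided power spectrum of a trace
#'
#' Power of bin k is the squared magnitude |X_k|^2 of the unnormalized DFT of
#' the first \code{fft_size} samples (mean removed). Any fixed normalization
#' cancels in the SNAVF ratio; this convention is documented so absolute
#' AVFs / AVFn values are reproducible. Parseval's identity in this
#' convention reads \code{sum_k |X_k|^2 = fft_size * sum_t x_t^2} over the
#' full two-sided spectrum.
#'
#' @param trace a \code{\link{pixel_trace}} or numeric vector.
#' @param fps sampling rate, required for a bare vector.
#' @param cfg a \code{\link{band_config}}.
#' @param demean subtract the segment mean before transforming (default TRUE).
#' @return A data frame with columns \code{freq} (Hz, bins 0..fft_size/2) and
#'   \code{power}.
#' @export
power_spectrum <- function(trace, fps = NULL, cfg = band_config(),
                           demean = TRUE) {
  seg <- .segment(trace, fps, cfg, demean)
  n <- cfg$fft_size
  x <- fft(seg$s)
  k <- 0:(n %/% 2)
  data.frame(freq = k * seg$fps / n, power = Mod(x[k + 1L])^2)
}

# Logical keep-mask over the full two-sided FFT, symmetric so that masked
# inversion returns a real signal. Band edges are inclusive.
.fft_mask <- function(nfft, fps, band) {
  k <- 0:(nfft - 1L)
  f <- pmin(k, nfft - k) * fps / nfft
  f >= band[1] & f <= band[2]
}

#' FFT band-pass filter
#'
#' Transforms the first \code{fft_size} samples, zeroes every bin whose
#' frequency falls outside \code{[lo, hi]} (conjugate-symmetric bins handled
#' together, so the output is real), and inverts. Sinusoids on the bin grid
#' pass or are blocked exactly.
#'
#' @param trace a \code{\link{pixel_trace}} or numeric vector.
#' @param band \code{c(lo, hi)} in Hz, inclusive edges.
#' @param fps sampling rate for a bare vector.
#' @param cfg a \code{\link{band_config}} (supplies \code{fft_size}).
#' @return A \code{\link{pixel_trace}} of length \code{fft_size}.
#' @export
band_pass <- function(trace, band, fps = NULL, cfg = band_config()) {
  seg <- .segment(trace, fps, cfg, demean = FALSE)
  .check_band_nyquist(band, seg$fps)
  x <- fft(seg$s)
  x[!.fft_mask(cfg$fft_size, seg$fps, band)] <- 0
  y <- Re(fft(x, inverse = TRUE)) / cfg$fft_size
  org <- if (inherits(trace, "pixel_trace")) trace$origin else c(NA, NA)
  ks <- if (inherits(trace, "pixel_trace")) trace$kernel_size else 1L
  pixel_trace(y, seg$fps, origin = org, kernel_size = ks)
}

# Fundamental + harmonic bookkeeping shared by signal_power / snavf_sweep.
.signal_bins <- function(p, fps, cfg) {
  n <- cfg$fft_size
  kmax <- n %/% 2
  freq <- (0:kmax) * fps / n
  in_band <- which(freq >= cfg$signal_band[1] & freq <= cfg$signal_band[2])
  if (length(in_band) == 0L) stop("signal band contains no FFT bins")
  if (all(p[in_band] == 0))
    return(list(avfs = 0, f0 = NA_real_))
  k0 <- in_band[which.max(p[in_band])] - 1L           # 0-based fundamental bin
  kh <- intersect(unique(pmin(kmax, pmax(1L, 2L * k0 + (-1:1)))), 1:kmax)
  harmonic <- max(p[kh + 1L])
  list(avfs = p[k0 + 1L] + harmonic, f0 = k0 * fps / n)
}

#' Pulse-band signal power AVFs
#'
#' Locates the fundamental as the largest-power bin inside the signal band
#' (1-5 Hz), then adds the power at the second harmonic: the largest bin
#' within one bin of twice the fundamental frequency. The harmonic is
#' counted even when 2 f0 exceeds the band's upper edge, since the signal is
#' defined as fundamental plus second harmonic rather than as all in-band
#' energy. An all-zero trace yields 0.
#'
#' @inheritParams power_spectrum
#' @param details if TRUE, return a list with \code{avfs} and the detected
#'   \code{fundamental_freq} (Hz) instead of a bare number.
#' @return Signal power (squared-magnitude units), or a list when
#'   \code{details = TRUE}.
#' @export
signal_power <- function(trace, fps = NULL, cfg = band_config(),
                         details = FALSE) {
  seg <- .segment(trace, fps, cfg)
  .check_band_nyquist(cfg$signal_band, seg$fps)
  p <- Mod(fft(seg$s)[1:(cfg$fft_size %/% 2 + 1L)])^2
  r <- .signal_bins(p, seg$fps, cfg)
  if (details) list(avfs = r$avfs, fundamental_freq = r$f0) else r$avfs
}

#' Noise-band power AVFn
#'
#' Sum of the \code{n_noise_peaks} (default two) largest bin powers among
#' bins whose frequency lies in the noise band (10-19 Hz).
#'
#' @inheritParams power_spectrum
#' @return Noise power (same units as \code{\link{signal_power}}).
#' @export
noise_power <- function(trace, fps = NULL, cfg = band_config()) {
  seg <- .segment(trace, fps, cfg)
  .check_band_nyquist(cfg$noise_band, seg$fps)
  p <- Mod(fft(seg$s)[1:(cfg$fft_size %/% 2 + 1L)])^2
  freq <- (0:(cfg$fft_size %/% 2)) * seg$fps / cfg$fft_size
  pb <- p[freq >= cfg$noise_band[1] & freq <= cfg$noise_band[2]]
  if (length(pb) == 0L) stop("noise band contains no FFT bins")
  sum(sort(pb, decreasing = TRUE)[seq_len(min(cfg$n_noise_peaks, length(pb)))])
}

#' Sweep kernel sizes and quantify the AVF condition
#'
#' For each kernel size N, filters the stack with the uniform N x N
#' moving-average kernel (exploiting linearity, implemented as the window
#' mean at the ROI), extracts the trace at \code{roi}, and computes AVFs,
#' AVFn and their ratio. SNAVF is the maximum ratio over the sweep and
#' \code{optimal_n} the kernel attaining it; ties (within a relative 1e-9)
#' go to the smallest N, the cheapest filter.
#'
#' @param stack a \code{\link{scalar_stack}} (normally luminance).
#' @param roi \code{c(row, col)}, 1-based; must lie in the valid region of
#'   the largest kernel in \code{sizes}.
#' @param sizes odd kernel sizes (default \code{\link{kernel_sweep_sizes}()},
#'   1 to 201 step 2).
#' @param cfg a \code{\link{band_config}}.
#' @return An object of class \code{snavf_sweep}: list with \code{table}
#'   (data frame: kernel_size, signal_power, noise_power, ratio,
#'   fundamental_freq), \code{optimal_n}, \code{snavf}, \code{roi},
#'   \code{cfg}. If some AVFn is exactly 0 (noise-free synthetic input) the
#'   ratio is reported as \code{Inf} with a warning.
#' @examples
#' ph <- generate_phantom(phantom_config(height = 41, width = 41,
#'                                       vessel_halfwidth = 8,
#'                                       shadow_halfwidth = 6, duration = 7))
#' lum <- to_channel(ph$stack, "luminance")
#' sw <- snavf_sweep(lum, roi = c(21, 21), sizes = c(1, 5, 9))
#' sw$optimal_n
#' @export
snavf_sweep <- function(stack, roi, sizes = kernel_sweep_sizes(),
                        cfg = band_config()) {
  stopifnot(inherits(stack, "scalar_stack"))
  d <- dim(stack$values)
  if (d[1] < cfg$fft_size)
    stop("stack has ", d[1], " frames; quantification needs >= ", cfg$fft_size)
  sizes <- sort(as.integer(sizes))
  for (n in sizes) .check_roi(roi, n, d[2], d[3])
  .check_band_nyquist(cfg$signal_band, stack$fps)
  .check_band_nyquist(cfg$noise_band, stack$fps)

  z <- .integral_stack(stack$values)
  nfft <- cfg$fft_size
  kmax <- nfft %/% 2
  freq <- (0:kmax) * stack$fps / nfft
  noise_idx <- which(freq >= cfg$noise_band[1] & freq <= cfg$noise_band[2])

  res <- lapply(sizes, function(n) {
    k <- (n - 1L) / 2L
    tr <- if (n == 1L) stack$values[, roi[1], roi[2]]
          else .window_mean(z, roi[1], roi[2], k)
    s <- tr[seq_len(nfft)]
    s <- s - mean(s)
    if (cfg$window == "hann")
      s <- s * (0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1L) / nfft))
    p <- Mod(fft(s)[1:(kmax + 1L)])^2
    sig <- .signal_bins(p, stack$fps, cfg)
    avfn <- sum(sort(p[noise_idx], decreasing = TRUE)[
      seq_len(min(cfg$n_noise_peaks, length(noise_idx)))])
    c(avfs = sig$avfs, avfn = avfn, f0 = sig$f0)
  })
  res <- do.call(rbind, res)
  ratio <- ifelse(res[, "avfn"] == 0, Inf, res[, "avfs"] / res[, "avfn"])
  if (any(!is.finite(ratio)))
    warning("AVFn = 0 for some kernel sizes (noise-free input); ",
            "ratio reported as Inf")
  best <- max(ratio)
  opt_i <- if (is.finite(best)) which(ratio >= best * (1 - 1e-9))[1]
           else which(!is.finite(ratio))[1]
  structure(list(
    table = data.frame(kernel_size = sizes, signal_power = res[, "avfs"],
                       noise_power = res[, "avfn"], ratio = ratio,
                       fundamental_freq = res[, "f0"]),
    optimal_n = sizes[opt_i], snavf = ratio[opt_i], roi = roi, cfg = cfg),
    class = "snavf_sweep")
}

#' @export
print.snavf_sweep <- function(x, ...) {
  cat(sprintf("<snavf_sweep> %d kernel sizes %d..%d at roi (%d, %d)\n",
              nrow(x$table), min(x$table$kernel_size),
              max(x$table$kernel_size), x$roi[1], x$roi[2]))
  cat(sprintf("  SNAVF = %.4g at optimal N = %d (fundamental %.3g Hz)\n",
              x$snavf, x$optimal_n,
              x$table$fundamental_freq[x$table$kernel_size == x$optimal_n]))
  invisible(x)
}

#' @export
as.data.frame.snavf_sweep <- function(x, ...) x$table

#' Phase opposition between two traces
#'
#' Pearson correlation between the two signal-band band-passed traces.
#' Values near -1 indicate the reversed-phase relationship seen between a
#' vessel's parietal surface and its lateral shadow.
#'
#' @param a,b traces of equal length (\code{\link{pixel_trace}} or numeric).
#' @param band band in Hz over which to compare (default the 1-5 Hz signal
#'   band).
#' @param fps sampling rate for bare vectors.
#' @param cfg a \code{\link{band_config}}.
#' @return Correlation in \code{[-1, 1]}.
#' @export
phase_opposition <- function(a, b, band = c(1, 5), fps = NULL,
                             cfg = band_config()) {
  ta <- .trace_samples(a, fps); tb <- .trace_samples(b, fps)
  if (length(ta$samples) != length(tb$samples))
    stop("traces must have equal length")
  xa <- band_pass(ta$samples, band, fps = ta$fps, cfg = cfg)$samples
  xb <- band_pass(tb$samples, band, fps = tb$fps, cfg = cfg)$samples
  if (sd(xa) == 0 || sd(xb) == 0)
    stop("undefined correlation: a band-passed trace has zero variance")
  cor(xa, xb)
}

#' Band-pass every pixel of a stack
#'
#' Applies the FFT band-pass of \code{\link{band_pass}} to every pixel's
#' trace at once; the result holds the first \code{fft_size} frames of
#' in-band luminance change, ready for \code{\link{render_sequence}}.
#'
#' @param stack a \code{\link{scalar_stack}} with at least \code{fft_size}
#'   frames.
#' @param band \code{c(lo, hi)} in Hz.
#' @param cfg a \code{\link{band_config}}.
#' @return A \code{scalar_stack} of \code{fft_size} frames with a
#'   \code{"band"} attribute.
#' @export
band_pass_stack <- function(stack, band = c(1, 5), cfg = band_config()) {
  stopifnot(inherits(stack, "scalar_stack"))
  d <- dim(stack$values)
  nfft <- cfg$fft_size
  if (d[1] < nfft)
    stop("stack has ", d[1], " frames; band-pass needs >= ", nfft)
  .check_band_nyquist(band, stack$fps)
  m <- stack$values[seq_len(nfft), , , drop = FALSE]
  dim(m) <- c(nfft, d[2] * d[3])
  x <- mvfft(m)
  x[!.fft_mask(nfft, stack$fps, band), ] <- 0
  y <- Re(mvfft(x, inverse = TRUE)) / nfft
  dim(y) <- c(nfft, d[2], d[3])
  out <- scalar_stack(y, stack$channel_kind, stack$fps, stack$pixel_pitch)
  attr(out, "band") <- band
  out
}
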