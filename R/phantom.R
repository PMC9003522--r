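# Synthetic AVF video phantom.
#
# The phantom emulates the physical mechanism of the non-contact recording:
# the fistula pulse wave observed by the camera is a displacement signal.
# When arterial ejection distends the anastomosis, the vessel's parietal
# (top) surface moves toward the camera and brightens, while the vessel's
# growing silhouette darkens flanking skin -- an anti-phase "shadow". The
# per-pixel luminance model is
#
#   vessel:   baseline + heartbeat(t) + thrill(t) + noise
#   shadow:   baseline - shadow_gain * heartbeat(t) + noise
#   elsewhere: baseline + noise
#
# with heartbeat(t) = heartbeat_amp * [sin(2 pi f0 t)
#                                      + harmonic_ratio * sin(4 pi f0 t)]
# and thrill(t) a single tone at thrill_freq (5-10 Hz, the palpable
# turbulence band), present only over the vessel.

#' Phantom scene configuration
#'
#' Parameterizes the synthetic AVF scene: acquisition (frame rate, duration),
#' waveform components, scene geometry (a vertical vessel strip flanked by
#' two anti-phase shadow bands) and per-pixel sensor noise.
#'
#' Defaults reproduce the study acquisition (40 fps, 10 s) with a 113-pixel
#' wide in-phase vessel (half-width 56). The heartbeat fundamental (1.25 Hz,
#' 75 bpm) and thrill tone (6.25 Hz) sit exactly on the 256-point FFT grid at
#' 40 fps, so neither leaks rectangular-window sidelobe power into the
#' 10-19 Hz noise band -- matching the premise that the noise band is free of
#' pulse and thrill energy.
#'
#' @param height,width frame size in pixels.
#' @param fps frame rate (Hz, default 40).
#' @param duration recording length (s, default 10).
#' @param f0 heartbeat fundamental (Hz, must lie in [1, 5]).
#' @param heartbeat_amp heartbeat amplitude (luminance units).
#' @param harmonic_ratio 2nd-harmonic amplitude relative to the fundamental.
#' @param thrill_freq thrill tone frequency (Hz, nominally 5-10).
#' @param thrill_amp thrill amplitude (luminance units), vessel only.
#' @param vessel_center column of the vessel axis (default: frame center).
#' @param vessel_halfwidth vessel half-width in pixels; in-phase width is
#'   \code{2 * vessel_halfwidth + 1}.
#' @param shadow_halfwidth width in pixels of each flanking shadow band.
#' @param shadow_gain anti-phase amplitude ratio (> 0) of the shadow.
#' @param baseline mean luminance (0-255).
#' @param noise_sigma per-pixel i.i.d. Gaussian noise SD (luminance units).
#' @param drift_amp,drift_freq optional global ambient-light drift tone
#'   (amplitude in luminance units, frequency in Hz; default off).
#' @param seed RNG seed; identical configs give bit-identical stacks.
#' @param quantize round frames to 8-bit integers (default TRUE). Disable for
#'   tests of exact spectral identities, which need unquantized traces.
#'
#' @return A validated list of class \code{phantom_config}.
#' @export
phantom_config <- function(height = 221L, width = 221L, fps = 40, duration = 10,
                           f0 = 1.25, heartbeat_amp = 3, harmonic_ratio = 0.3,
                           thrill_freq = 6.25, thrill_amp = 1,
                           vessel_center = NULL, vessel_halfwidth = 56L,
                           shadow_halfwidth = 30L, shadow_gain = 1,
                           baseline = 120, noise_sigma = 2,
                           drift_amp = 0, drift_freq = 0,
                           seed = 1L, quantize = TRUE) {
  if (is.null(vessel_center)) vessel_center <- (width + 1L) %/% 2L
  cfg <- structure(as.list(environment()), class = "phantom_config")
  validate_phantom_config(cfg)
}

#' Validate a phantom configuration
#'
#' Enforces the geometric and spectral invariants: the fundamental lies in
#' [1, 5] Hz, vessel and shadow bands fit inside the frame, amplitudes are
#' non-negative, and warns when component summation could exceed [0, 255]
#' (clipping distorts spectra).
#'
#' @param cfg a \code{phantom_config}.
#' @return \code{cfg} on success.
#' @export
validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (height < 1 || width < 1) stop("frame dimensions must be positive")
    if (fps <= 0 || duration <= 0) stop("fps and duration must be positive")
    if (f0 < 1 || f0 > 5) stop("f0 must lie in [1, 5] Hz")
    amps <- c(heartbeat_amp, harmonic_ratio, thrill_amp, shadow_gain,
              noise_sigma, drift_amp)
    if (any(amps < 0)) stop("amplitudes must be non-negative")
    lo <- vessel_center - vessel_halfwidth - shadow_halfwidth
    hi <- vessel_center + vessel_halfwidth + shadow_halfwidth
    if (lo < 1 || hi > width)
      stop("vessel and shadow regions must fit inside the frame")
    swing <- heartbeat_amp * (1 + harmonic_ratio) * max(1, shadow_gain) +
      thrill_amp + drift_amp + 4 * noise_sigma
    if (baseline + swing > 255 || baseline - swing < 0)
      warning("phantom components may clip at [0, 255]; clipping distorts spectra")
  })
  cfg
}

#' Generate a synthetic AVF video phantom
#'
#' Renders the configured scene to an RGB \code{\link{frame_stack}} (gray
#' frames: the three channels carry identical values, so luminance equals the
#' modeled signal) and returns it together with the noiseless ground truth.
#'
#' @param config a \code{\link{phantom_config}}.
#' @return A list with elements:
#'   \describe{
#'     \item{stack}{the \code{frame_stack} (\code{round(fps * duration)}
#'       frames).}
#'     \item{truth}{a list with \code{traces} (data frame of time, noiseless
#'       heartbeat / thrill / drift components and the parietal and shadow
#'       pixel traces) and \code{masks} (logical \code{height x width}
#'       matrices \code{vessel}, \code{shadow}, \code{background}).}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_config(height = 31, width = 31,
#'                                       vessel_halfwidth = 6,
#'                                       shadow_halfwidth = 4, duration = 0.5))
#' dim(ph$stack$frames)  # 20 frames
#' @export
generate_phantom <- function(config) {
  cfg <- validate_phantom_config(config)
  nt <- as.integer(round(cfg$fps * cfg$duration))
  tvec <- (seq_len(nt) - 1L) / cfg$fps
  heartbeat <- cfg$heartbeat_amp *
    (sin(2 * pi * cfg$f0 * tvec) +
       cfg$harmonic_ratio * sin(4 * pi * cfg$f0 * tvec))
  thrill <- cfg$thrill_amp * sin(2 * pi * cfg$thrill_freq * tvec)
  drift <- if (cfg$drift_amp > 0)
    cfg$drift_amp * sin(2 * pi * cfg$drift_freq * tvec) else numeric(nt)

  dcol <- abs(seq_len(cfg$width) - cfg$vessel_center)
  vessel_cols <- dcol <= cfg$vessel_halfwidth
  shadow_cols <- !vessel_cols & dcol <= cfg$vessel_halfwidth + cfg$shadow_halfwidth
  profile <- numeric(cfg$width)
  profile[vessel_cols] <- 1
  profile[shadow_cols] <- -cfg$shadow_gain

  # (t, col) signal, constant down each column; thrill only over the vessel.
  sig_tc <- outer(heartbeat, profile) + outer(thrill, as.numeric(vessel_cols))
  a <- aperm(array(sig_tc, c(nt, cfg$width, cfg$height)), c(1L, 3L, 2L))
  a <- a + cfg$baseline + drift  # drift recycles along t (first dimension)
  if (cfg$noise_sigma > 0) {
    a <- a + withr::with_seed(cfg$seed,
                              array(rnorm(length(a), sd = cfg$noise_sigma), dim(a)))
  }
  if (cfg$quantize) {
    a <- round(a)
    n_clip <- sum(a < 0 | a > 255)
    if (n_clip > 0)
      warning(n_clip, " pixel values clipped to [0, 255]")
    a <- pmin(pmax(a, 0), 255)
  }
  frames <- array(a, c(dim(a), 3L))  # gray: identical channels
  if (cfg$quantize) storage.mode(frames) <- "integer"

  masks <- list(
    vessel = matrix(vessel_cols, cfg$height, cfg$width, byrow = TRUE),
    shadow = matrix(shadow_cols, cfg$height, cfg$width, byrow = TRUE),
    background = matrix(!(vessel_cols | shadow_cols), cfg$height, cfg$width,
                        byrow = TRUE))
  traces <- data.frame(
    time = tvec, heartbeat = heartbeat, thrill = thrill, drift = drift,
    parietal = cfg$baseline + heartbeat + thrill + drift,
    shadow = cfg$baseline - cfg$shadow_gain * heartbeat + drift)

  list(stack = frame_stack(frames, fps = cfg$fps,
                           subject_id = "synthetic-phantom",
                           meta = list(config = unclass(cfg))),
       truth = list(traces = traces, masks = masks, config = cfg))
}

#' Export phantom ground truth to plain-text files
#'
#' Writes the noiseless component traces as CSV and the region masks as
#' 1-bit PNG images.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{generate_phantom}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("traces.csv", "mask_vessel.png", "mask_shadow.png",
                            "mask_background.png"))
  write.csv(truth$traces, paths[1], row.names = FALSE)
  for (i in 1:3) {
    png::writePNG(truth$masks[[i]] * 1, paths[i + 1])
  }
  invisible(paths)
}
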