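# Independent brute-force oracles and small fixtures shared across tests.

# Literal double-loop moving average (valid region), the reference the fast
# integral-image implementation must match.
bf_moving_average <- function(mat, n, m = n, weights = NULL) {
  h <- nrow(mat); w <- ncol(mat)
  hv <- h - n + 1L; wv <- w - m + 1L
  out <- matrix(0, hv, wv)
  for (i in seq_len(hv)) {
    for (j in seq_len(wv)) {
      win <- mat[i:(i + n - 1L), j:(j + m - 1L)]
      out[i, j] <- if (is.null(weights)) mean(win) else sum(win * weights)
    }
  }
  out
}

# Direct DFT bin power by explicit summation (no fft()), for a 0-based bin k.
bf_bin_power <- function(x, k) {
  n <- length(x)
  t <- 0:(n - 1L)
  re <- sum(x * cos(2 * pi * k * t / n))
  im <- -sum(x * sin(2 * pi * k * t / n))
  re^2 + im^2
}

# Quartiles by the half-median rule, written independently via index
# arithmetic on the sorted vector.
bf_quartiles <- function(v) {
  s <- sort(v); n <- length(s)
  mid <- function(u) {
    k <- length(u)
    if (k %% 2 == 1L) u[(k + 1L) / 2L] else (u[k / 2L] + u[k / 2L + 1L]) / 2
  }
  half <- floor(n / 2)
  c(mid(s[1:half]), mid(s), mid(s[(n - half + 1L):n]), s[n])
}

# A small, fast phantom: 61 x 61 frames, 280 samples (>= the 256-point FFT),
# 31-px in-phase vessel. Geometry scaled down; waveform model unchanged.
small_phantom_config <- function(...) {
  phantom_config(height = 61L, width = 61L, duration = 7,
                 vessel_halfwidth = 15L, shadow_halfwidth = 8L, ...)
}

# An 8-bit RGB test stack with reproducible random content.
random_stack <- function(nt = 4L, h = 8L, w = 8L, seed = 42L, fps = 40) {
  withr::with_seed(seed, {
    frame_stack(array(sample(0:255, nt * h * w * 3, replace = TRUE),
                      c(nt, h, w, 3)), fps = fps)
  })
}
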