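# On the 256-point grid at 40 fps the bin spacing is 0.15625 Hz; 2.5 Hz is
# bin 16 and 12.5 Hz is bin 80, so these tones are exactly representable.
tone <- function(freq, amp = 1, fps = 40, n = 280, phase = 0) {
  amp * sin(2 * pi * freq * (0:(n - 1)) / fps + phase)
}

test_that("on-grid tones pass or are blocked exactly by the FFT band-pass", {
  x_in <- tone(2.5)
  x_out <- tone(12.5)
  bp <- band_pass(x_in, c(1, 5), fps = 40)
  expect_equal(bp$samples, x_in[1:256], tolerance = 1e-9)
  expect_equal(max(abs(band_pass(x_out, c(1, 5), fps = 40)$samples)), 0,
               tolerance = 1e-9)
  # superposition: the filter isolates the in-band component
  both <- band_pass(x_in + x_out, c(1, 5), fps = 40)
  expect_equal(both$samples, x_in[1:256], tolerance = 1e-9)
  expect_error(band_pass(x_in, c(1, 25), fps = 40), "Nyquist")
  expect_error(band_pass(tone(2.5, n = 100), c(1, 5), fps = 40), "too short")
})

test_that("complementary band-passes reconstruct the analyzed segment", {
  withr::with_seed(21, {
    x <- rnorm(280)
    lo <- band_pass(x, c(0, 0.9375), fps = 40)$samples
    mid <- band_pass(x, c(1, 5), fps = 40)$samples
    hi <- band_pass(x, c(5.15625, 20), fps = 40)$samples
    expect_equal(lo + mid + hi, x[1:256], tolerance = 1e-9)
  })
})

test_that("signal power sums fundamental and second-harmonic bin powers", {
  # pure on-grid tone of amplitude a: bin power (n * a / 2)^2, verified
  # against the explicit DFT summation oracle
  a <- 1.7
  x <- tone(2.5, amp = a)
  expect_equal(signal_power(x, fps = 40), (256 * a / 2)^2, tolerance = 1e-9)
  expect_equal(signal_power(x, fps = 40),
               bf_bin_power(x[1:256] - mean(x[1:256]), 16), tolerance = 1e-9)
  # fundamental + harmonic: both bins counted
  xh <- tone(2.5, amp = a) + tone(5, amp = 0.4 * a)
  expect_equal(signal_power(xh, fps = 40),
               (256 * a / 2)^2 + (256 * 0.4 * a / 2)^2, tolerance = 1e-8)
  d <- signal_power(xh, fps = 40, details = TRUE)
  expect_equal(d$fundamental_freq, 2.5)
  expect_equal(signal_power(rep(0, 256), fps = 40), 0)
  # a tone outside 1-5 Hz leaves only numerical noise in the band
  expect_lt(signal_power(tone(12.5), fps = 40), 1e-15 * (256 / 2)^2)
})

test_that("noise power sums the two largest components in 10-19 Hz", {
  x <- tone(12.5, amp = 2) + tone(15, amp = 1)
  p1 <- (256 * 2 / 2)^2
  p2 <- (256 * 1 / 2)^2
  expect_equal(noise_power(x, fps = 40), p1 + p2, tolerance = 1e-9)
  expect_equal(noise_power(x, fps = 40),
               bf_bin_power(x[1:256], 80) + bf_bin_power(x[1:256], 96),
               tolerance = 1e-9)
  # single tone: the second-largest bin adds essentially nothing
  expect_equal(noise_power(tone(12.5, amp = 2), fps = 40), p1,
               tolerance = 1e-6)
  expect_equal(noise_power(rep(0, 256), fps = 40), 0)
  # out-of-noise-band tones are ignored
  expect_lt(noise_power(tone(2.5, amp = 5), fps = 40), 1e-12 * p1)
})

test_that("Parseval's identity holds for the reported power convention", {
  withr::with_seed(22, {
    for (rep in 1:20) {
      x <- rnorm(280)
      p <- power_spectrum(x, fps = 40, demean = FALSE)$power
      total <- p[1] + p[129] + 2 * sum(p[2:128])
      expect_equal(total, 256 * sum(x[1:256]^2), tolerance = 1e-9)
    }
  })
})

test_that("the SNR ratio is invariant to positive rescaling of the trace", {
  withr::with_seed(23, {
    x <- tone(2.5, amp = 3) + rnorm(280, sd = 0.5)
    r1 <- signal_power(x, fps = 40) / noise_power(x, fps = 40)
    r2 <- signal_power(17 * x, fps = 40) / noise_power(17 * x, fps = 40)
    expect_equal(r1, r2, tolerance = 1e-9)
  })
})

test_that("a spatially uniform stack gives an N-independent ratio, smallest kernel wins", {
  trace <- tone(2.5, amp = 3) + tone(12.5, amp = 0.4) + 100
  vals <- array(rep(trace, times = 11 * 11), c(280, 11, 11))
  sc <- scalar_stack(vals, "luminance", 40)
  sw <- snavf_sweep(sc, roi = c(6, 6), sizes = c(1, 3, 5, 7, 9, 11))
  expect_lt(diff(range(sw$table$ratio)) / sw$snavf, 1e-9)
  expect_identical(sw$optimal_n, 1L)
})

test_that("an exactly noise-free stack yields the infinity sentinel with a warning", {
  vals <- array(100, c(280, 9, 9))  # constant: every band power is exactly 0
  sc <- scalar_stack(vals, "luminance", 40)
  expect_warning(sw <- snavf_sweep(sc, roi = c(5, 5), sizes = c(1, 3)),
                 "AVFn = 0")
  expect_identical(sw$snavf, Inf)
  expect_identical(sw$optimal_n, 1L)
})

test_that("the sweep matches a brute-force per-kernel recomputation", {
  ph <- generate_phantom(small_phantom_config(seed = 5))
  lum <- to_channel(ph$stack, "luminance")
  sizes <- c(1L, 5L, 11L, 17L)
  sw <- snavf_sweep(lum, roi = c(31, 31), sizes = sizes)
  for (i in seq_along(sizes)) {
    n <- sizes[i]
    k <- (n - 1L) / 2L
    tr <- vapply(seq_len(dim(lum$values)[1]), function(t)
      mean(lum$values[t, (31 - k):(31 + k), (31 - k):(31 + k)]), 0)
    expect_equal(sw$table$signal_power[i], signal_power(tr, fps = 40),
                 tolerance = 1e-9)
    expect_equal(sw$table$noise_power[i], noise_power(tr, fps = 40),
                 tolerance = 1e-9)
  }
  expect_equal(sw$snavf, max(sw$table$ratio))
  expect_identical(sw$optimal_n,
                   sw$table$kernel_size[which.max(sw$table$ratio)])
})

test_that("phase opposition is +1 for a trace against itself, -1 against its negation", {
  withr::with_seed(24, {
    x <- tone(1.25, amp = 2) + rnorm(280, sd = 0.2)
    expect_equal(phase_opposition(x, x, fps = 40), 1, tolerance = 1e-12)
    expect_equal(phase_opposition(x, -x, fps = 40), -1, tolerance = 1e-12)
    expect_error(phase_opposition(x, rep(0, 280), fps = 40),
                 "undefined correlation")
    expect_error(phase_opposition(x, x[1:270], fps = 40), "equal length")
  })
})

test_that("band-passing a whole stack agrees with per-trace filtering", {
  ph <- generate_phantom(phantom_config(height = 9, width = 9,
                                        vessel_halfwidth = 2,
                                        shadow_halfwidth = 1, duration = 7,
                                        seed = 2))
  lum <- to_channel(ph$stack, "luminance")
  bp <- band_pass_stack(lum, c(1, 5))
  expect_identical(dim(bp$values), c(256L, 9L, 9L))
  one <- band_pass(lum$values[, 4, 7], c(1, 5), fps = 40)$samples
  expect_equal(bp$values[, 4, 7], one, tolerance = 1e-9)
})
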