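test_that("frame stacks round-trip losslessly through TIFF and raw formats", {
  fs <- random_stack()
  for (fmt in c("tiff", "raw")) {
    path <- withr::local_tempfile(fileext = if (fmt == "tiff") ".tiff" else ".raw")
    write_frame_stack(fs, path, fmt = fmt)
    back <- read_frame_stack(path)
    expect_identical(dim(back$frames), dim(fs$frames))
    expect_equal(as.vector(back$frames), as.vector(fs$frames),
                 tolerance = 0, ignore_attr = TRUE)
  }
})

test_that("sidecar metadata preserves acquisition parameters", {
  fs <- random_stack(fps = 40)
  path <- withr::local_tempfile(fileext = ".raw")
  write_frame_stack(fs, path)
  back <- read_frame_stack(path)
  expect_equal(back$fps, 40)
  expect_equal(back$pixel_pitch, 0.08)
})

test_that("raw dialect re-reads byte-identically", {
  ph <- generate_phantom(phantom_config(height = 15, width = 15,
                                        vessel_halfwidth = 3,
                                        shadow_halfwidth = 2, duration = 0.5))
  p1 <- withr::local_tempfile(fileext = ".raw")
  p2 <- withr::local_tempfile(fileext = ".raw")
  write_frame_stack(ph$stack, p1)
  write_frame_stack(read_frame_stack(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("malformed inputs fail with descriptive errors", {
  expect_error(read_frame_stack("no/such/file.raw"), "not found")
  fs <- random_stack()
  expect_error(write_frame_stack(fs, "x.mp4"), "format")
  expect_error(frame_stack(list(array(0, c(4, 4, 3)), array(0, c(5, 4, 3))),
                           fps = 40),
               "inconsistent frame geometry")
  expect_error(frame_stack(array(300, c(1, 2, 2, 3)), fps = 40), "0, 255")
  expect_error(frame_stack(array(0, c(1, 2, 2, 3)), fps = 0), "fps")
  # raw file whose length contradicts its sidecar geometry
  path <- withr::local_tempfile(fileext = ".raw")
  write_frame_stack(fs, path)
  writeBin(as.raw(0:9), path)
  expect_error(read_frame_stack(path), "inconsistent frame geometry")
})

test_that("phantom frame count equals fps times duration", {
  cfg <- phantom_config(height = 21, width = 21, vessel_halfwidth = 4,
                        shadow_halfwidth = 3, fps = 40, duration = 10)
  ph <- generate_phantom(cfg)
  expect_identical(dim(ph$stack$frames)[1], 400L)
  expect_equal(nrow(ph$truth$traces), 400)
})

test_that("noiseless phantom pixels follow the constructed waveform exactly", {
  cfg <- phantom_config(height = 21, width = 21, vessel_halfwidth = 4,
                        shadow_halfwidth = 3, duration = 1, noise_sigma = 0,
                        shadow_gain = 0, thrill_amp = 0, quantize = FALSE)
  ph <- generate_phantom(cfg)
  tvec <- ph$truth$traces$time
  expected <- cfg$baseline + cfg$heartbeat_amp *
    (sin(2 * pi * cfg$f0 * tvec) +
       cfg$harmonic_ratio * sin(4 * pi * cfg$f0 * tvec))
  center <- ph$stack$frames[, 11, 11, 1]
  expect_equal(center, expected, tolerance = 1e-12)
  # background column carries baseline only
  expect_equal(ph$stack$frames[, 11, 1, 1], rep(cfg$baseline, 40))
})

test_that("identical seeds reproduce the stack bit for bit, different seeds do not", {
  cfg1 <- phantom_config(height = 15, width = 15, vessel_halfwidth = 3,
                         shadow_halfwidth = 2, duration = 0.5, seed = 7)
  a <- generate_phantom(cfg1)$stack$frames
  b <- generate_phantom(cfg1)$stack$frames
  expect_identical(a, b)
  cfg2 <- phantom_config(height = 15, width = 15, vessel_halfwidth = 3,
                         shadow_halfwidth = 2, duration = 0.5, seed = 8)
  expect_false(identical(a, generate_phantom(cfg2)$stack$frames))
})

test_that("parietal and shadow pixels are exactly anti-phase without noise", {
  cfg <- phantom_config(height = 21, width = 21, vessel_halfwidth = 4,
                        shadow_halfwidth = 3, duration = 2, noise_sigma = 0,
                        thrill_amp = 0, quantize = FALSE)
  ph <- generate_phantom(cfg)
  parietal <- ph$stack$frames[, 11, 11, 1]
  shadow <- ph$stack$frames[, 11, 11 + cfg$vessel_halfwidth + 2, 1]
  expect_equal(cor(parietal, shadow), -1, tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(phantom_config(f0 = 0.5), "f0")
  expect_error(phantom_config(height = 21, width = 21, vessel_halfwidth = 15,
                              shadow_halfwidth = 3),
               "fit inside")
  expect_error(phantom_config(heartbeat_amp = -1), "non-negative")
  expect_warning(phantom_config(height = 21, width = 21, vessel_halfwidth = 4,
                                shadow_halfwidth = 3, baseline = 250),
                 "clip")
})
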