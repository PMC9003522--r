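test_that("color map endpoints, midpoint and cardinality follow the quantization rule", {
  cm <- build_colormap("blue-red", -2, 2)
  expect_length(cm$colors, 256)
  expect_identical(length(unique(cm$colors)), 256L)
  expect_identical(map_to_levels(-2, cm), 0L)
  expect_identical(map_to_levels(2, cm), 255L)
  expect_identical(map_to_levels(0, cm), 128L)  # documented midpoint rule
  # out-of-domain clamps to the end levels
  expect_identical(map_to_levels(c(-10, 10), cm), c(0L, 255L))
  expect_error(build_colormap("blue-red", 1, 1), "vmin")
  # a full-range ramp exercises every one of the 256 levels
  ramp <- seq(-2, 2, length.out = 256)
  expect_identical(sort(unique(map_to_levels(ramp, cm))), 0:255)
})

test_that("level index is monotone in the input", {
  cm <- build_colormap("blue-red", -1, 1)
  withr::with_seed(31, {
    v <- sort(runif(500, -1.2, 1.2))
    lv <- map_to_levels(v, cm)
    expect_true(all(diff(lv) >= 0))
  })
})

test_that("an all-zero stack renders as a single mid-level color", {
  sc <- scalar_stack(array(0, c(3, 4, 4)), "luminance", 40)
  fr <- render_sequence(sc)
  px <- unique(matrix(fr, ncol = 3))
  expect_identical(nrow(px), 1L)
  mid <- grDevices::col2rgb(attr(fr, "cmap")$colors[129])
  expect_identical(as.integer(px), as.integer(mid))
})

test_that("scaling is global: equal values get equal colors in every frame", {
  withr::with_seed(32, {
    v <- array(rnorm(5 * 3 * 3), c(5, 3, 3))
    v[2, 1, 1] <- 0.42
    v[5, 3, 2] <- 0.42
    fr <- render_sequence(scalar_stack(v, "luminance", 40))
    expect_identical(fr[2, 1, 1, ], fr[5, 3, 2, ])
  })
})

test_that("opposite phases of the pulse land on opposite palette halves", {
  ph <- generate_phantom(phantom_config(height = 15, width = 15,
                                        vessel_halfwidth = 3,
                                        shadow_halfwidth = 2, duration = 7,
                                        noise_sigma = 0.2, seed = 4))
  lum <- to_channel(ph$stack, "luminance")
  bp <- band_pass_stack(lum, c(1, 5))
  cmap <- build_colormap("blue-red", -max(abs(bp$values)), max(abs(bp$values)))
  vessel_trace <- bp$values[, 8, 8]
  t_hi <- which.max(vessel_trace)
  t_lo <- which.min(vessel_trace)
  lv <- map_to_levels(bp$values[c(t_hi, t_lo), 8, 8], cmap)
  expect_gt(lv[1], 128)   # tense phase: blue half
  expect_lt(lv[2], 128)   # relaxed phase: red half
  # shadow pixel sits on the opposite half from the vessel at the same instant
  lv_shadow <- map_to_levels(bp$values[t_hi, 8, 13], cmap)
  expect_lt(lv_shadow, 128)
  fr <- render_sequence(bp, cmap = cmap, t_range = c(t_hi, t_lo))
  expect_identical(dim(fr), c(2L, 15L, 15L, 3L))
  expect_error(render_sequence(bp, t_range = integer(0)), "at least one")
  expect_error(render_sequence(bp, t_range = 1000), "outside")
})

test_that("rendered frames export to PNG and re-read identically", {
  sc <- scalar_stack(array(rnorm(2 * 4 * 4), c(2, 4, 4)), "luminance", 40)
  fr <- render_sequence(sc)
  dir <- withr::local_tempdir()
  paths <- write_frames_png(fr, dir)
  expect_length(paths, 2)
  back <- round(png::readPNG(paths[1]) * 255)
  expect_equal(as.vector(back), as.vector(fr[1, , , ]), ignore_attr = TRUE)
})
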