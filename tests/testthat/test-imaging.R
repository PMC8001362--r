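# Image loading, calibration, histogram matching, and Lab conversion.

test_that("loading attaches the magnification-derived pixel scale", {
  set.seed(1)
  f <- write_tmp_png(array(runif(10 * 10 * 3), c(10, 10, 3)))
  img1 <- load_image(f, magnification = 1)
  expect_equal(img1$microns_per_pixel, 4.54)
  img100 <- load_image(f, magnification = 100)
  expect_equal(img100$microns_per_pixel, 0.0454)
  # linearity: doubling magnification halves the scale exactly
  for (m in c(20, 100, 250)) {
    a <- load_image(f, magnification = m)
    b <- load_image(f, magnification = 2 * m)
    expect_identical(b$microns_per_pixel, a$microns_per_pixel / 2)
  }
  # resize factor scales linearly
  expect_equal(load_image(f, 100, resize_factor = 2752 / 1920)$microns_per_pixel,
               4.54 * (2752 / 1920) / 100)
})

test_that("alpha channels are dropped and grayscale replicated", {
  set.seed(2)
  rgba <- array(runif(8 * 6 * 4), c(8, 6, 4))
  img <- load_image(write_tmp_png(rgba), magnification = 100)
  expect_equal(dim(img$pixels), c(8L, 6L, 3L))
  expect_equal(img$pixels, round(rgba[, , 1:3] * 255))
  gray <- matrix(runif(12), 4, 3)
  img_g <- load_image(write_tmp_png(gray), magnification = 100)
  expect_equal(img_g$pixels[, , 1], img_g$pixels[, , 3])
})

test_that("unreadable files and invalid calibration raise classed errors", {
  expect_error(load_image(tempfile(fileext = ".png"), 100),
               class = "steatoquant_io_error")
  bad <- tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(load_image(bad, 100), class = "steatoquant_io_error")
  f <- write_tmp_png(matrix(runif(9), 3, 3))
  expect_error(load_image(f, magnification = -10),
               class = "steatoquant_domain_error")
  expect_error(load_image(f, magnification = 0),
               class = "steatoquant_domain_error")
})

test_that("histogram matching is the identity on self and maps constants", {
  set.seed(3)
  x <- calibrated_image(array(sample(0:255, 40 * 30 * 3, TRUE), c(40, 30, 3)), 100)
  expect_equal(match_histogram(x, x)$pixels, x$pixels)
  const_in <- calibrated_image(array(50, c(5, 5, 3)), 100)
  ref_px <- array(0, c(5, 5, 3))
  ref_px[, , 1] <- 200; ref_px[, , 2] <- 100; ref_px[, , 3] <- 25
  const_ref <- calibrated_image(ref_px, 100)
  out <- match_histogram(const_in, const_ref)
  expect_equal(unique(as.vector(out$pixels[, , 1])), 200)
  expect_equal(unique(as.vector(out$pixels[, , 2])), 100)
  expect_equal(unique(as.vector(out$pixels[, , 3])), 25)
})

test_that("matched channels reproduce the reference CDF within 2/256", {
  set.seed(4)
  img <- calibrated_image(array(sample(0:255, 200 * 200 * 3, TRUE), c(200, 200, 3)), 100)
  ref_px <- array(pmin(pmax(round(rnorm(150 * 150 * 3, 120, 40)), 0), 255),
                  c(150, 150, 3))
  ref <- calibrated_image(ref_px, 100)
  out <- match_histogram(img, ref)
  expect_equal(dim(out$pixels), dim(img$pixels))
  expect_equal(out$microns_per_pixel, img$microns_per_pixel)
  for (ch in 1:3) {
    cdf_out <- cumsum(tabulate(out$pixels[, , ch] + 1, 256)) / (200 * 200)
    cdf_ref <- cumsum(tabulate(ref$pixels[, , ch] + 1, 256)) / (150 * 150)
    expect_lt(max(abs(cdf_out - cdf_ref)), 2 / 256)
  }
  # idempotence: matching twice equals matching once within one intensity step
  out2 <- match_histogram(out, ref)
  expect_lte(max(abs(out2$pixels - out$pixels)), 1)
})

test_that("Lab conversion hits the standard D65 closed form", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(0, 0, 0)
  px[1, 2, ] <- c(255, 255, 255)
  px[1, 3, ] <- c(255, 0, 0)
  lab <- rgb_to_cielab(calibrated_image(px, 100))$lab
  expect_equal(lab[1, 1, ], c(0, 0, 0), tolerance = 1e-8)
  expect_lt(abs(lab[1, 2, 1] - 100), 1e-6)
  expect_lte(lab[1, 2, 1], 100)
  expect_lt(max(abs(lab[1, 2, 2:3])), 0.01)
  expect_equal(unname(lab[1, 3, ]),
               unname(oracle_srgb_to_lab(255, 0, 0)), tolerance = 5e-4)
  # random 8-bit colors against the scalar oracle, to 3 decimals
  set.seed(5)
  cols <- matrix(sample(0:255, 60, TRUE), ncol = 3)
  got <- rgb_to_cielab(calibrated_image(array(cols, c(nrow(cols), 1, 3)), 100))$lab
  for (i in seq_len(nrow(cols))) {
    expect_equal(unname(got[i, 1, ]),
                 unname(oracle_srgb_to_lab(cols[i, 1], cols[i, 2], cols[i, 3])),
                 tolerance = 5e-4)
  }
})

test_that("Lab values stay in gamut bounds and invert to RGB within 1 step", {
  grid <- as.matrix(expand.grid(r = seq(0, 255, length.out = 16),
                                g = seq(0, 255, length.out = 16),
                                b = seq(0, 255, length.out = 16)))
  grid <- round(grid)
  img <- calibrated_image(array(grid, c(nrow(grid), 1, 3)), 100)
  lab <- rgb_to_cielab(img)$lab
  expect_true(all(lab[, , 1] >= 0 & lab[, , 1] <= 100))
  expect_true(all(abs(lab[, , 2:3]) <= 128))
  for (i in seq(1, nrow(grid), by = 37)) {
    back <- oracle_lab_to_srgb(lab[i, 1, 1], lab[i, 1, 2], lab[i, 1, 3])
    expect_lte(max(abs(back - grid[i, ])), 1)
  }
})

test_that("mask and overlay writers round-trip through PNG", {
  set.seed(6)
  mask <- matrix(rbinom(30 * 20, 1, 0.3), 30, 20)
  f <- tempfile(fileext = ".png")
  write_mask_png(mask, f)
  expect_identical(read_mask_png(f), mask + 0L)
  img <- calibrated_image(array(sample(0:255, 30 * 20 * 3, TRUE), c(30, 20, 3)), 100)
  fo <- tempfile(fileext = ".png")
  write_overlay_png(img, mask, fo)
  expect_true(file.exists(fo))
  lbl <- matrix(sample(0:5, 30 * 20, TRUE), 30, 20)
  ft <- tempfile(fileext = ".tif")
  write_label_tiff(lbl, ft)
  expect_equal(round(tiff::readTIFF(ft) * 65535), lbl)
})
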