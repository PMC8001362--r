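# Mask cleanup, watershed separation, and ME quantification.

disc_mask <- function(H, W, cr, cc, r) {
  xy <- expand.grid(row = 1:H, col = 1:W)
  matrix(as.integer((xy$row - cr)^2 + (xy$col - cc)^2 <= r^2), H, W)
}

test_that("the macrovesicle cutoff doubles the mean nuclear area", {
  expect_equal(macrovesicle_cutoff(73.356), 146.71)
  expect_equal(macrovesicle_cutoff(0), 0)
  expect_equal(macrovesicle_cutoff(50), 100)
  expect_error(macrovesicle_cutoff(-1), class = "steatoquant_domain_error")
})

test_that("component labeling is 8-connected", {
  m <- matrix(0, 5, 5)
  m[2, 2] <- 1; m[3, 3] <- 1   # diagonal touch: one component
  expect_equal(max(label_components(m)), 1L)
  m2 <- matrix(0, 5, 5)
  m2[1, 1] <- 1; m2[5, 5] <- 1
  expect_equal(max(label_components(m2)), 2L)
  # areas partition the foreground
  set.seed(40)
  r <- matrix(rbinom(50 * 50, 1, 0.4), 50, 50)
  lab <- label_components(r)
  expect_equal(sum(lab > 0), sum(r))
  expect_equal(sort(unique(as.vector(lab[lab > 0]))), seq_len(max(lab)))
})

test_that("mask cleanup removes specks and fills holes, never eroding objects", {
  expect_equal(postprocess_mask(matrix(0, 10, 10), 5, TRUE), matrix(0, 10, 10))
  speck <- matrix(0, 10, 10); speck[5, 5:7] <- 1
  expect_true(all(postprocess_mask(speck, min_object_px = 5) == 0))
  expect_equal(postprocess_mask(speck, min_object_px = 3, fill_holes = FALSE),
               speck)
  holed <- disc_mask(21, 21, 11, 11, 7); holed[11, 11] <- 0L
  filled <- postprocess_mask(holed, 0, fill_holes = TRUE)
  expect_equal(filled, oracle_fill_holes(holed))
  expect_equal(filled[11, 11], 1L)
  # random masks: output never adds foreground outside oracle-filled holes
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rbinom(30 * 30, 1, 0.35), 30, 30)
    out <- postprocess_mask(m, min_object_px = 4, fill_holes = TRUE)
    expect_true(all(out[oracle_fill_holes(m) == 0] == 0))
  }
})

test_that("watershed keeps convex blobs whole and splits touching discs", {
  one <- disc_mask(60, 60, 30, 30, 20)
  lab <- watershed_separate(one)
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab == 1L), sum(one))
  two <- disc_mask(80, 80, 40, 25, 20) | disc_mask(80, 80, 40, 55, 20)
  two <- two + 0
  lab2 <- watershed_separate(two, min_sep_px = 10)
  expect_equal(max(lab2), 2L)
  expect_equal(sum(lab2 > 0), sum(two))     # partition: no pixel lost
  expect_equal(sum(tabulate(lab2[lab2 > 0])), sum(two))
  empty <- watershed_separate(matrix(0, 10, 10))
  expect_equal(max(empty), 0L)
  expect_equal(dim(empty), c(10L, 10L))
})

test_that("quantification reports areas, macro flags, and ME percentage", {
  H <- 40; W <- 50
  img <- calibrated_image(array(128, c(H, W, 3)), magnification = 1)  # 4.54 um/px
  mpp <- img$microns_per_pixel
  lab <- matrix(0L, H, W)
  lab[1:10, 1:20] <- 1L    # 200 px region
  rep1 <- quantify_steatosis(lab, img, cutoff_um2 = 0)
  expect_equal(rep1$me_percent, 100 * 200 / (H * W))
  expect_equal(rep1$fat_area_um2, 200 * mpp^2)
  expect_equal(rep1$macro_area_um2, rep1$fat_area_um2)   # cutoff 0: all macro
  # cutoff above every region: nothing macro but fat area persists
  rep2 <- quantify_steatosis(lab, img, cutoff_um2 = 201 * mpp^2)
  expect_equal(rep2$n_macro, 0L)
  expect_equal(rep2$me_percent, 0)
  expect_gt(rep2$fat_area_um2, 0)
  # region table consistency
  expect_equal(sum(rep1$regions$area_px), sum(lab > 0))
  expect_error(quantify_steatosis(matrix(0L, 5, 5), img, 10),
               class = "steatoquant_domain_error")
  expect_error(quantify_steatosis(lab, img, -1),
               class = "steatoquant_domain_error")
})

test_that("ME percentage is scale-free while areas scale with calibration", {
  set.seed(41)
  mask <- (disc_mask(50, 60, 20, 20, 10) | disc_mask(50, 60, 35, 45, 8)) + 0
  lab <- watershed_separate(mask)
  img_m <- calibrated_image(array(0, c(50, 60, 3)), magnification = 100)
  img_2m <- calibrated_image(array(0, c(50, 60, 3)), magnification = 200)
  r_m <- quantify_steatosis(lab, img_m, cutoff_um2 = 0)
  r_2m <- quantify_steatosis(lab, img_2m, cutoff_um2 = 0)
  expect_equal(r_m$me_percent, r_2m$me_percent)
  expect_equal(r_m$fat_area_um2, 4 * r_2m$fat_area_um2)
})

test_that("adding macro foreground never decreases the ME percentage", {
  img <- calibrated_image(array(0, c(60, 60, 3)), magnification = 1)
  base <- disc_mask(60, 60, 20, 20, 10)
  grown <- base | disc_mask(60, 60, 45, 45, 8)
  me <- function(m) quantify_steatosis(watershed_separate(m + 0), img, 0)$me_percent
  expect_gte(me(grown), me(base))
})

test_that("reports serialize to JSON and CSV", {
  img <- calibrated_image(array(0, c(10, 10, 3)), 100)
  lab <- matrix(0L, 10, 10); lab[1:3, 1:3] <- 1L
  rep <- quantify_steatosis(lab, img, cutoff_um2 = 0)
  fj <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  write_report(rep, fj, fc)
  j <- jsonlite::read_json(fj)
  expect_equal(j$me_percent, rep$me_percent)
  expect_equal(utils::read.csv(fc)$n_vacuoles, rep$n_vacuoles)
})
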