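# Training, prediction, evaluation, and persistence of the six pixel
# classifiers.

algorithms <- c("knn", "svm", "rf", "nb", "nn", "dense-nn")

test_that("every algorithm separates well-separated color clusters", {
  tab <- make_separable_table(1000, seed = 21)
  sp <- stratified_split(tab, 0.7, seed = 1)
  for (alg in algorithms) {
    clf <- train_pixel_classifier(alg, sp$train, seed = 2)
    acc <- mean(predict(clf, sp$test) == sp$test$labels)
    expect_gte(acc, 0.99)
    expect_gte(evaluate_classifier(clf, sp$test)$auc, 0.999)
  }
})

test_that("degenerate tables and unknown algorithms are rejected", {
  single <- feature_table(matrix(runif(60, 0, 255), 10, 6), rep(0L, 10))
  expect_error(train_pixel_classifier("knn", single, seed = 1),
               class = "steatoquant_domain_error")
  tab <- make_separable_table(100)
  expect_error(train_pixel_classifier("boosted-stump", tab, seed = 1),
               class = "steatoquant_domain_error")
})

test_that("training is reproducible for a fixed seed", {
  tab <- make_separable_table(600, seed = 22, sd = 25)
  probe <- make_separable_table(200, seed = 23, sd = 40)
  for (alg in algorithms) {
    p1 <- predict(train_pixel_classifier(alg, tab, seed = 9), probe, type = "prob")
    p2 <- predict(train_pixel_classifier(alg, tab, seed = 9), probe, type = "prob")
    expect_identical(p1, p2)
  }
})

test_that("KNN memorizes training pixels and masks are thread-invariant", {
  set.seed(30)
  px <- array(0, c(12, 15, 3))
  vac <- c(230, 140, 40)
  for (ch in 1:3) px[, , ch] <- vac[ch]
  img <- calibrated_image(px, 100)
  lab <- rgb_to_cielab(img)
  # training set contains that exact color as class 1
  feats <- rbind(c(vac, oracle_srgb_to_lab(vac[1], vac[2], vac[3])),
                 matrix(c(runif(30 * 3, 0, 120),
                          runif(30 * 3, -50, 90)), 30, 6))
  tab <- feature_table(feats, c(1L, rep(0L, 30)))
  clf <- train_pixel_classifier("knn", tab, seed = 1, config = list(k = 1L))
  m1 <- predict_mask(clf, img, lab, n_threads = 1)
  expect_true(all(m1 == 1))
  m8 <- predict_mask(clf, img, lab, n_threads = 8)
  expect_identical(m1, m8)
})

test_that("mask prediction validates dimensions and thread count", {
  sl <- make_slide(seed = 31, dims = c(40L, 50L))
  lab_other <- rgb_to_cielab(calibrated_image(array(10, c(30, 50, 3)), 100))
  clf <- train_pixel_classifier("nb", make_separable_table(200), seed = 1)
  expect_error(predict_mask(clf, sl$image, lab_other),
               class = "steatoquant_domain_error")
  expect_error(predict_mask(clf, sl$image, rgb_to_cielab(sl$image), n_threads = 0),
               class = "steatoquant_domain_error")
})

test_that("AUC matches hand-computed and pair-counting values", {
  train <- make_separable_table(400, seed = 24)
  clf <- train_pixel_classifier("nb", train, seed = 1)
  ev <- evaluate_classifier(clf, make_separable_table(100, seed = 25))
  expect_gte(ev$auc, 0)
  expect_lte(ev$auc, 1)
  rp <- ev$roc_points
  expect_equal(rp$fpr[1], 0); expect_equal(rp$tpr[1], 0)
  expect_equal(rp$fpr[nrow(rp)], 1); expect_equal(rp$tpr[nrow(rp)], 1)
  expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))
  # the documented worked example: labels (1,1,0,0), scores (.9,.4,.6,.1)
  expect_equal(steatoquant:::roc_auc(c(0.9, 0.4, 0.6, 0.1),
                                     c(1L, 1L, 0L, 0L))$auc, 0.75)
  expect_equal(steatoquant:::roc_auc(c(1, 1, 0, 0), c(1L, 1L, 0L, 0L))$auc, 1.0)
  expect_equal(steatoquant:::roc_auc(rep(0.4, 6),
                                     c(1L, 0L, 1L, 0L, 1L, 0L))$auc, 0.5)
  # random scores with ties vs exhaustive pair counting and pROC
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:50, 1)
    y <- c(1L, 0L, rbinom(n - 2, 1, 0.5))
    sc <- sample(seq(0, 1, by = 0.1), n, TRUE)
    expect_equal(steatoquant:::roc_auc(sc, y)$auc, oracle_auc_pairs(sc, y),
                 tolerance = 1e-12)
    expect_equal(steatoquant:::roc_auc(sc, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_error(evaluate_classifier(clf,
                 feature_table(matrix(runif(36, 0, 255), 6, 6), rep(1L, 6))),
               class = "steatoquant_domain_error")
})

test_that("models survive a save/load round trip for every algorithm", {
  train <- make_separable_table(400, seed = 26, sd = 20)
  probe <- make_separable_table(100, seed = 27, sd = 30)
  test_tab <- make_separable_table(120, seed = 28, sd = 40)
  for (alg in algorithms) {
    clf <- train_pixel_classifier(alg, train, seed = 3)
    f <- tempfile(fileext = ".stqmodel")
    save_model(clf, f)
    back <- load_model(f)
    expect_identical(predict(back, probe), predict(clf, probe))
    expect_equal(evaluate_classifier(back, test_tab)$auc,
                 evaluate_classifier(clf, test_tab)$auc)
  }
})

test_that("corrupt or truncated model files give a format error", {
  expect_error(load_model(tempfile()), class = "steatoquant_io_error")
  f <- tempfile()
  clf <- train_pixel_classifier("nb", make_separable_table(100), seed = 1)
  save_model(clf, f)
  raw_bytes <- readBin(f, "raw", file.info(f)$size)
  trunc <- tempfile()
  writeBin(raw_bytes[1:20], trunc)
  expect_error(load_model(trunc), class = "steatoquant_format_error")
  junk <- tempfile()
  saveRDS(list(foo = 1), junk)
  expect_error(load_model(junk), class = "steatoquant_format_error")
})

test_that("the dense network has exactly 56 trainable parameters", {
  clf <- train_pixel_classifier("dense-nn", make_separable_table(200), seed = 1)
  expect_identical(clf$n_parameters, 56L)
  st <- clf$fitted_state
  expect_equal(dim(st$params$W1), c(6L, 6L))
  expect_equal(dim(st$params$W2), c(6L, 2L))
})
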