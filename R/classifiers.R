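# The six pixel-classification backends behind one S3 model class.

ALGORITHMS <- c("knn", "svm", "rf", "nb", "nn", "dense-nn")

default_config <- function(algorithm) {
  switch(algorithm,
    knn = list(k = 5L),
    svm = list(cost = 1, gamma = NULL),      # gamma = 1/(6 * var) at fit time
    rf = list(ntree = 100L, mtry = 2L),      # floor(sqrt(6)) features per split
    nb = list(),
    nn = list(hidden = 100L, activation = "relu", optimizer = "adam",
              lr = 0.001, epochs = 100L, batch_size = 256L),
    `dense-nn` = list(hidden = 6L, activation = "sigmoid",
                      optimizer = "adamax", lr = 0.002, epochs = 100L,
                      batch_size = 256L),
    stop_domain("unknown algorithm '%s' (choose one of %s)", algorithm,
                paste(ALGORITHMS, collapse = ", ")))
}

#' Train a pixel classifier
#'
#' Fits one of six interchangeable per-pixel classifiers on a six-channel
#' color [feature_table]: k-nearest neighbors (`knn`, k = 5), RBF support
#' vector machine (`svm`, C = 1, gamma = 1/(6 * feature variance)), random
#' forest (`rf`, 100 trees), Gaussian naive Bayes (`nb`), a single-hidden-layer
#' neural network (`nn`, 100 ReLU units trained with Adam), and a minimal
#' dense network (`dense-nn`) with exactly 6 sigmoid hidden units and a
#' 2-unit softmax output trained with Adamax on cross-entropy loss.
#'
#' Features are fed unscaled by default; set `config$standardize = TRUE` to
#' z-score them using training statistics.
#'
#' @param algorithm one of `"knn","svm","rf","nb","nn","dense-nn"`.
#' @param table a [feature_table] containing both classes.
#' @param seed integer seed controlling any training stochasticity
#'   (rf bootstrap, network initialization and batching).
#' @param config named list of overrides for the algorithm's pinned defaults.
#' @return an object of class `pixel_classifier` with fields `algorithm`,
#'   `fitted_state`, `feature_order`, and `train_meta`
#'   (`n_pixels`, `seed`, `train_time_seconds`).
#' @export
train_pixel_classifier <- function(algorithm, table, seed = 0L,
                                   config = list()) {
  stopifnot(inherits(table, "feature_table"))
  cfg <- utils::modifyList(default_config(algorithm), config)
  if (length(unique(table$labels)) < 2L)
    stop_domain("training table must contain both classes")
  X <- table$features
  y <- table$labels
  std <- NULL
  if (isTRUE(cfg$standardize)) {
    std <- list(center = colMeans(X), scale = pmax(apply(X, 2, stats::sd), 1e-9))
    X <- scale(X, std$center, std$scale)
  }
  t0 <- proc.time()[["elapsed"]]
  state <- switch(algorithm,
    knn = list(X = X, y = factor(y, levels = c(0L, 1L)), k = cfg$k),
    svm = {
      gamma <- if (is.null(cfg$gamma)) 1 / (6 * stats::var(as.vector(X))) else cfg$gamma
      fit <- e1071::svm(X, factor(y, levels = c(0L, 1L)), kernel = "radial",
                        cost = cfg$cost, gamma = gamma, scale = FALSE)
      # orient decision values so positive favors class 1
      dv <- attr(stats::predict(fit, X[1:min(50L, nrow(X)), , drop = FALSE],
                                decision.values = TRUE), "decision.values")
      flip <- identical(colnames(dv)[1], "0/1")
      list(fit = fit, flip = flip)
    },
    rf = with_seed(seed, randomForest::randomForest(
      X, factor(y, levels = c(0L, 1L)), ntree = cfg$ntree, mtry = cfg$mtry)),
    nb = e1071::naiveBayes(X, factor(y, levels = c(0L, 1L))),
    nn = ,
    `dense-nn` = mlp_train(X, y, hidden = cfg$hidden,
                           activation = cfg$activation,
                           optimizer = cfg$optimizer, lr = cfg$lr,
                           epochs = cfg$epochs, batch_size = cfg$batch_size,
                           seed = seed))
  elapsed <- proc.time()[["elapsed"]] - t0
  obj <- structure(list(
    algorithm = algorithm,
    fitted_state = state,
    feature_order = c("R", "G", "B", "L", "a", "b"),
    standardize = std,
    config = cfg,
    train_meta = list(n_pixels = table$n, seed = as.integer(seed),
                      train_time_seconds = elapsed)
  ), class = "pixel_classifier")
  if (algorithm %in% c("nn", "dense-nn")) obj$n_parameters <- state$n_parameters
  obj
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> algorithm: %s, trained on %d pixels (seed %d, %.3f s)\n",
              x$algorithm, x$train_meta$n_pixels, x$train_meta$seed,
              x$train_meta$train_time_seconds))
  invisible(x)
}

#' @export
summary.pixel_classifier <- function(object, ...) {
  print(object)
  cat("feature order:", paste(object$feature_order, collapse = ", "), "\n")
  if (!is.null(object$n_parameters))
    cat("trainable parameters:", object$n_parameters, "\n")
  cat("standardized features:", !is.null(object$standardize), "\n")
  invisible(object)
}

# Continuous class-1 score and hard 0/1 label for a raw feature matrix.
# Hard labels are argmax of the class scores with exact ties resolved to 0.
predict_core <- function(object, X) {
  colnames(X) <- object$feature_order
  if (!is.null(object$standardize))
    X <- scale(X, object$standardize$center, object$standardize$scale)
  st <- object$fitted_state
  switch(object$algorithm,
    knn = {
      pr <- class::knn(st$X, X, st$y, k = st$k, prob = TRUE, use.all = TRUE)
      pwin <- attr(pr, "prob")
      p1 <- ifelse(pr == "1", pwin, 1 - pwin)
      list(score = p1, label = (p1 > 0.5) + 0L)
    },
    svm = {
      dv <- attr(stats::predict(st$fit, X, decision.values = TRUE),
                 "decision.values")[, 1]
      if (st$flip) dv <- -dv
      list(score = dv, label = (dv > 0) + 0L)
    },
    rf = {
      p1 <- stats::predict(st, X, type = "prob")[, "1"]
      list(score = p1, label = (p1 > 0.5) + 0L)
    },
    nb = {
      p1 <- stats::predict(st, X, type = "raw")[, "1"]
      list(score = p1, label = (p1 > 0.5) + 0L)
    },
    nn = ,
    `dense-nn` = {
      p1 <- mlp_predict_prob(st, X)
      list(score = p1, label = (p1 > 0.5) + 0L)
    })
}

#' Predict classes or scores for a feature table
#' @param object a `pixel_classifier`.
#' @param newdata a [feature_table] or an `n x 6` feature matrix in the order
#'   `R,G,B,L,a,b`.
#' @param type `"class"` for hard 0/1 labels, `"prob"` for the continuous
#'   class-1 score.
#' @param ... unused.
#' @export
predict.pixel_classifier <- function(object, newdata,
                                     type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_table")) newdata$features else newdata
  if (!is.matrix(X) || ncol(X) != 6L)
    stop_domain("newdata must have 6 feature columns (R,G,B,L,a,b)")
  res <- predict_core(object, X)
  if (type == "class") res$label else res$score
}

#' Classify every pixel of an image into a binary fat-vacuole mask
#'
#' The image is partitioned into contiguous row blocks processed
#' independently (optionally in parallel); because each pixel is classified
#' independently and blocks are re-assembled in order, the output mask is
#' bit-identical for every thread count.
#'
#' @param classifier a trained `pixel_classifier`.
#' @param image a [calibrated_image].
#' @param lab the matching `lab_image`.
#' @param n_threads number of worker processes (>= 1).
#' @return binary `H x W` matrix, 1 = fat vacuole.
#' @export
predict_mask <- function(classifier, image, lab, n_threads = 1L) {
  stopifnot(inherits(classifier, "pixel_classifier"),
            inherits(image, "calibrated_image"), inherits(lab, "lab_image"))
  d <- dim(image)
  if (!all(d == dim(lab))) stop_domain("image/lab dimension mismatch")
  if (n_threads < 1L) stop_domain("n_threads must be >= 1")
  H <- d[1]
  k <- min(n_threads, H)
  blocks <- split(seq_len(H), ceiling(seq_len(H) / ceiling(H / k)))
  classify_rows <- function(rs) {
    X <- cbind(as.vector(image$pixels[rs, , 1]), as.vector(image$pixels[rs, , 2]),
               as.vector(image$pixels[rs, , 3]),
               as.vector(lab$lab[rs, , 1]), as.vector(lab$lab[rs, , 2]),
               as.vector(lab$lab[rs, , 3]))
    matrix(predict_core(classifier, X)$label, nrow = length(rs))
  }
  parts <- if (n_threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(blocks, classify_rows, mc.cores = n_threads)
  } else {
    lapply(blocks, classify_rows)
  }
  do.call(rbind, parts)
}

#' Evaluate a classifier on a held-out feature table
#'
#' Computes the ROC curve from the continuous class-1 scores and its area by
#' the trapezoid rule (equivalent to the normalized Mann-Whitney U statistic,
#' score ties counted 1/2).
#'
#' @param classifier a trained `pixel_classifier`.
#' @param test a non-empty [feature_table] with both classes present.
#' @return object of class `evaluation_result`: list with `auc`,
#'   `roc_points` (`data.frame` of `fpr`, `tpr`), and `n_test`.
#' @export
evaluate_classifier <- function(classifier, test) {
  stopifnot(inherits(test, "feature_table"))
  if (length(unique(test$labels)) < 2L)
    stop_domain("AUC undefined: test set contains a single class")
  score <- predict(classifier, test, type = "prob")
  roc_auc(score, test$labels, n_test = test$n)
}

# ROC from scores; ties grouped at equal thresholds.
roc_auc <- function(score, labels, n_test = length(labels)) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- labels[ord]
  n1 <- sum(y == 1L); n0 <- length(y) - n1
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y == 1L)[grp_end]
  fp <- cumsum(y == 0L)[grp_end]
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(auc = auc,
                 roc_points = data.frame(fpr = fpr, tpr = tpr),
                 n_test = n_test),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> AUC = %.4f on %d test pixels\n",
              x$auc, x$n_test))
  invisible(x)
}

MODEL_FORMAT_VERSION <- 1L

#' Persist / restore a trained pixel classifier
#'
#' Models are stored as a single file carrying a version header
#' (`format_version`, `algorithm`, `feature_order`, `train_meta`) plus the
#' fitted state; the round trip preserves predictions exactly.
#'
#' @param classifier a `pixel_classifier`.
#' @param path file path.
#' @export
save_model <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  payload <- list(format_version = MODEL_FORMAT_VERSION,
                  algorithm = classifier$algorithm,
                  feature_order = classifier$feature_order,
                  train_meta = classifier$train_meta,
                  classifier = classifier)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_io("model file not found: %s", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop_format("not a valid model file (%s): %s", conditionMessage(e), path))
  need <- c("format_version", "algorithm", "feature_order", "classifier")
  if (!is.list(payload) || !all(need %in% names(payload)))
    stop_format("model file is missing required header fields: %s", path)
  if (payload$format_version != MODEL_FORMAT_VERSION)
    stop_format("unsupported model format version %s (expected %d): %s",
                payload$format_version, MODEL_FORMAT_VERSION, path)
  payload$classifier
}
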