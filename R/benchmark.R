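# Experiment harnesses: training time/AUC across pixel budgets, and
# classification time across thread counts. Timings are reported, never
# asserted: they are hardware-dependent.

#' Training-time and AUC benchmark across pixel budgets
#'
#' For every (algorithm, budget) pair: subsample the budget, stratified
#' 70/30 split, train, evaluate on the held-out 30% — repeated `repeats`
#' times with per-repeat seeds `seed + repeat_index`, reporting means and
#' standard errors of wall-clock training time and AUC.
#'
#' @param table a [feature_table] to draw budgets from.
#' @param budgets pixel budgets (each `<= table$n`).
#' @param algorithms algorithm ids (see [train_pixel_classifier()]).
#' @param repeats repetitions per cell (>= 1).
#' @param seed base integer seed.
#' @param train_fraction proportion used for training (default 0.7).
#' @return `data.frame` with columns `model, pixels, average_time_s,
#'   average_auc, se_time, se_auc, repeats`.
#' @export
run_training_benchmark <- function(table, budgets, algorithms = ALGORITHMS,
                                   repeats = 10L, seed = 0L,
                                   train_fraction = 0.7) {
  stopifnot(inherits(table, "feature_table"))
  if (repeats < 1L) stop_domain("repeats must be >= 1")
  if (any(budgets > table$n))
    stop_domain("budget %d exceeds table size %d",
                max(budgets), table$n)
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  rows <- list()
  for (alg in algorithms) {
    for (b in budgets) {
      times <- numeric(repeats); aucs <- numeric(repeats)
      for (r in seq_len(repeats)) {
        rs <- as.integer(seed) + r
        sub <- subsample_features(table, b, seed = rs)
        sp <- stratified_split(sub, train_fraction, seed = rs)
        clf <- train_pixel_classifier(alg, sp$train, seed = rs)
        times[r] <- clf$train_meta$train_time_seconds
        aucs[r] <- evaluate_classifier(clf, sp$test)$auc
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = alg, pixels = b, average_time_s = mean(times),
        average_auc = mean(aucs), se_time = se(times), se_auc = se(aucs),
        repeats = repeats, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classification-time benchmark across thread counts
#'
#' Times [predict_mask()] for each image at each thread count and verifies
#' that the resulting masks are identical across thread counts.
#'
#' @param classifier a trained `pixel_classifier`.
#' @param images list of [calibrated_image]s.
#' @param thread_counts integer vector of worker counts.
#' @return `data.frame` with columns `model, image, threads, time_s`;
#'   attribute `hardware_dependent = TRUE` marks the timings as
#'   machine-specific.
#' @export
run_classification_benchmark <- function(classifier, images,
                                         thread_counts = c(1L, 2L, 4L, 6L, 8L, 10L)) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  rows <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    lab <- rgb_to_cielab(img)
    ref_mask <- NULL
    for (th in thread_counts) {
      t0 <- proc.time()[["elapsed"]]
      m <- predict_mask(classifier, img, lab, n_threads = th)
      dt <- proc.time()[["elapsed"]] - t0
      if (is.null(ref_mask)) ref_mask <- m
      else if (!identical(m, ref_mask))
        stop_domain("mask differs across thread counts for image %d", i)
      rows[[length(rows) + 1L]] <- data.frame(
        model = classifier$algorithm, image = i, threads = th, time_s = dt,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "hardware_dependent") <- TRUE
  out
}
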