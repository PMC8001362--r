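# Per-pixel color feature vectors from labeled windows; subsampling and
# stratified train/test splitting.

#' Construct a feature table
#'
#' A feature table holds one six-channel color vector `(R, G, B, L*, a*, b*)`
#' per pixel together with its binary class label (1 = fat vacuole,
#' 0 = non-vacuole). This is the unit of data every classifier trains on.
#'
#' @param features numeric `n x 6` matrix, columns in the fixed order
#'   `R, G, B, L, a, b`.
#' @param labels length-`n` vector of 0/1 labels.
#' @return object of class `feature_table` with fields `features`, `labels`,
#'   and row count `n`.
#' @export
feature_table <- function(features, labels) {
  if (!is.matrix(features) || ncol(features) != 6L)
    stop_domain("`features` must be an n x 6 matrix")
  if (length(labels) != nrow(features))
    stop_domain("`labels` length (%d) must equal feature rows (%d)",
                length(labels), nrow(features))
  if (!all(labels %in% c(0, 1)))
    stop_domain("labels must be binary 0/1")
  colnames(features) <- c("R", "G", "B", "L", "a", "b")
  structure(list(features = features, labels = as.integer(labels),
                 n = nrow(features)), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d pixels (%d fat, %d background)\n",
              x$n, sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Define a labeled training window
#'
#' Windows are axis-aligned rectangles assumed to lie entirely inside (label 1)
#' or outside (label 0) fat vacuoles. Coordinates are 0-based, row-major,
#' half-open: the window covers rows `row .. row+height-1`.
#'
#' @param image_id identifier of the source image.
#' @param row,col 0-based top-left pixel.
#' @param height,width window size in pixels.
#' @param label 0 or 1.
#' @return one-row `data.frame` with columns
#'   `image_id,row,col,height,width,label`.
#' @export
labeled_window <- function(image_id, row, col, height, width, label) {
  if (!label %in% c(0, 1)) stop_domain("window label must be 0 or 1")
  if (height < 1 || width < 1) stop_domain("window size must be positive")
  if (row < 0 || col < 0) stop_domain("window origin must be non-negative")
  data.frame(image_id = as.character(image_id), row = as.integer(row),
             col = as.integer(col), height = as.integer(height),
             width = as.integer(width), label = as.integer(label),
             stringsAsFactors = FALSE)
}

# Row-major linear indices (into an H x W matrix) of a window's pixels.
window_indices <- function(H, W, row, col, height, width) {
  if (row + height > H || col + width > W)
    stop_domain(paste0("window exceeds image bounds: origin (%d,%d), ",
                       "size (%d,%d), image %d x %d"),
                row, col, height, width, H, W)
  rows <- row + seq_len(height)       # 1-based
  cols <- col + seq_len(width)
  ridx <- rep(rows, each = width)
  cidx <- rep(cols, times = height)
  ridx + (cidx - 1L) * H
}

#' Extract per-pixel feature vectors from a labeled window
#'
#' Returns one row per window pixel, in raster order (row-major from the
#' window origin), each carrying the window's label.
#'
#' @param image a [calibrated_image].
#' @param lab the matching `lab_image` from [rgb_to_cielab()].
#' @param window a one-row window `data.frame` (see [labeled_window()]).
#' @param truth_mask optional binary ground-truth mask; if more than 5% of the
#'   window's pixels disagree with the window label a warning is issued
#'   (windows are supposed to be class-pure).
#' @return a [feature_table] with `height * width` rows.
#' @export
extract_window_pixels <- function(image, lab, window, truth_mask = NULL) {
  stopifnot(inherits(image, "calibrated_image"), inherits(lab, "lab_image"))
  d <- dim(image)
  if (!all(d == dim(lab))) stop_domain("lab image dimensions differ from image")
  idx <- window_indices(d[1], d[2], window$row, window$col,
                        window$height, window$width)
  feat <- cbind(image$pixels[, , 1][idx], image$pixels[, , 2][idx],
                image$pixels[, , 3][idx],
                lab$lab[, , 1][idx], lab$lab[, , 2][idx], lab$lab[, , 3][idx])
  if (!is.null(truth_mask)) {
    disagree <- mean(truth_mask[idx] != window$label)
    if (disagree > 0.05)
      warning(sprintf("window at (%d,%d) disagrees with truth mask on %.1f%% of pixels",
                      window$row, window$col, 100 * disagree))
  }
  feature_table(feat, rep(window$label, length(idx)))
}

#' Extract and stack feature vectors from many windows
#' @inheritParams extract_window_pixels
#' @param windows `data.frame` of windows, one per row.
#' @return a single [feature_table] with all windows' pixels stacked in order.
#' @export
extract_windows <- function(image, lab, windows, truth_mask = NULL) {
  tabs <- lapply(seq_len(nrow(windows)), function(i)
    extract_window_pixels(image, lab, windows[i, , drop = FALSE], truth_mask))
  feature_table(do.call(rbind, lapply(tabs, `[[`, "features")),
                unlist(lapply(tabs, `[[`, "labels")))
}

#' Draw a random pixel subset from a feature table
#'
#' Uniform sampling without replacement (non-stratified by default, matching
#' the training protocol in which only the train/test split is stratified).
#'
#' @param table a [feature_table].
#' @param n_pixels number of rows to keep, `1 <= n_pixels <= table$n`.
#' @param seed integer seed; draws are reproducible.
#' @param stratify if `TRUE`, sample each class proportionally instead.
#' @return a [feature_table] with `n_pixels` rows.
#' @export
subsample_features <- function(table, n_pixels, seed, stratify = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (n_pixels < 1 || n_pixels > table$n)
    stop_domain("n_pixels (%d) must be in [1, %d]", n_pixels, table$n)
  idx <- with_seed(seed, {
    if (!stratify) sample.int(table$n, n_pixels)
    else {
      pos <- which(table$labels == 1L); neg <- which(table$labels == 0L)
      npos <- floor(n_pixels * length(pos) / table$n + 0.5)
      c(sample(pos, min(npos, length(pos))),
        sample(neg, min(n_pixels - npos, length(neg))))
    }
  })
  feature_table(table$features[idx, , drop = FALSE], table$labels[idx])
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Splits a feature table so that each class contributes
#' `round(class_count * train_fraction)` rows (half-up rounding) to the
#' training side; train and test partition the rows exactly.
#'
#' @param table a [feature_table] containing both classes.
#' @param train_fraction proportion in (0, 1), e.g. 0.7.
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both [feature_table]s.
#' @export
stratified_split <- function(table, train_fraction, seed) {
  stopifnot(inherits(table, "feature_table"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_domain("train_fraction must be in (0, 1)")
  classes <- c(0L, 1L)
  counts <- vapply(classes, function(k) sum(table$labels == k), 1L)
  if (any(counts == 0L))
    stop_domain("stratification impossible: class %d has 0 rows",
                classes[counts == 0L][1])
  train_idx <- with_seed(seed, {
    unlist(lapply(classes, function(k) {
      rows <- which(table$labels == k)
      sample(rows, round_half_up(length(rows) * train_fraction))
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(table$n), train_idx)
  list(train = feature_table(table$features[train_idx, , drop = FALSE],
                             table$labels[train_idx]),
       test = feature_table(table$features[test_idx, , drop = FALSE],
                            table$labels[test_idx]))
}

#' Read / write labeled windows as CSV
#'
#' The CSV schema is `image_id,row,col,height,width,label` with 0-based
#' origins.
#' @param windows windows `data.frame`.
#' @param path CSV path.
#' @export
write_windows_csv <- function(windows, path) {
  utils::write.csv(windows[, c("image_id", "row", "col", "height", "width",
                               "label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  if (!file.exists(path)) stop_io("windows CSV not found: %s", path)
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "row", "col", "height", "width", "label")
  if (!all(need %in% names(w)))
    stop_format("windows CSV must have columns %s", paste(need, collapse = ","))
  w
}

#' Read / write a feature table as CSV (`R,G,B,L,a,b,label`)
#' @param table a [feature_table].
#' @param path CSV path.
#' @export
write_features_csv <- function(table, path) {
  df <- as.data.frame(table$features)
  df$label <- table$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop_io("feature CSV not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("R", "G", "B", "L", "a", "b", "label")
  if (!all(need %in% names(df)))
    stop_format("feature CSV must have columns %s", paste(need, collapse = ","))
  feature_table(as.matrix(df[, need[1:6]]), df$label)
}
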