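# Pixel-wise comparison of automatic vs manual masks and the four derived
# classification metrics.

#' Pixel-wise confusion counts between an automatic and a manual mask
#'
#' Per pixel: both 1 -> TP; auto 1 / manual 0 -> FP; both 0 -> TN;
#' auto 0 / manual 1 -> FN.
#'
#' @param auto binary `H x W` automatic mask.
#' @param manual binary `H x W` manual ground-truth mask of equal size.
#' @return object of class `confusion_counts`: list with integer `TP`, `FP`,
#'   `TN`, `FN` summing to the pixel count.
#' @export
compare_masks <- function(auto, manual) {
  if (!is_binary_mask(auto) || !is_binary_mask(manual))
    stop_domain("masks must be binary 0/1 matrices")
  if (!all(dim(auto) == dim(manual)))
    stop_domain("mask dimensions differ: %dx%d vs %dx%d",
                nrow(auto), ncol(auto), nrow(manual), ncol(manual))
  tp <- sum(auto == 1 & manual == 1)
  fp <- sum(auto == 1 & manual == 0)
  fn <- sum(auto == 0 & manual == 1)
  tn <- sum(auto == 0 & manual == 0)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Accuracy, sensitivity, specificity, and precision from confusion counts
#'
#' \deqn{Accuracy = (TP+TN)/(TP+FP+FN+TN)}
#' \deqn{Sensitivity = TP/(TP+FN)}
#' \deqn{Specificity = TN/(TN+FP)}
#' \deqn{Precision = TP/(TP+FP)}
#' A ratio whose denominator is zero is reported as `NA` (undefined), never
#' as a number.
#'
#' @param counts a `confusion_counts` object (or list with `TP,FP,TN,FN`).
#' @return named list `accuracy`, `sensitivity`, `specificity`, `precision`.
#' @export
confusion_metrics <- function(counts) {
  with(counts, {
    total <- TP + FP + TN + FN
    if (total == 0) stop_domain("all confusion counts are zero")
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    list(accuracy = (TP + TN) / total,
         sensitivity = ratio(TP, TP + FN),
         specificity = ratio(TN, TN + FP),
         precision = ratio(TP, TP + FP))
  })
}
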