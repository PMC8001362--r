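# From binary fat mask to separated vacuoles and an ME percentage report.

#' Macrovesicle size cutoff from mean nuclear area
#'
#' A fat vacuole counts as macrovesicular when it is at least twice the size
#' of a normal hepatocyte nucleus. With the reference mean nuclear area of
#' 73.356 um^2 (measured on hematoxylin-stained frozen sections) the cutoff
#' is 146.71 um^2.
#'
#' @param mean_nuclear_area_um2 mean nuclear cross-section area in um^2
#'   (>= 0).
#' @return `2 * mean_nuclear_area_um2`, rounded to 2 decimals.
#' @export
macrovesicle_cutoff <- function(mean_nuclear_area_um2) {
  if (!is.numeric(mean_nuclear_area_um2) || length(mean_nuclear_area_um2) != 1L ||
      !is.finite(mean_nuclear_area_um2) || mean_nuclear_area_um2 < 0)
    stop_domain("mean nuclear area must be a non-negative scalar")
  round_half_up(2 * mean_nuclear_area_um2 * 100) / 100
}

#' 8-connected component labeling of a binary mask
#' @param mask binary `H x W` matrix.
#' @return integer `H x W` label matrix (0 = background).
#' @export
label_components <- function(mask) {
  if (!is_binary_mask(mask)) stop_domain("`mask` must be a binary 0/1 matrix")
  .label8(mask + 0)
}

#' Clean a classifier mask before segmentation
#'
#' Removes 8-connected components smaller than `min_object_px` and optionally
#' fills interior holes. Never adds foreground outside filled holes.
#'
#' @param mask binary `H x W` matrix.
#' @param min_object_px components with fewer pixels are dropped.
#' @param fill_holes fill background cavities fully enclosed by foreground.
#' @return binary `H x W` matrix.
#' @export
postprocess_mask <- function(mask, min_object_px = 0L, fill_holes = TRUE) {
  if (!is_binary_mask(mask)) stop_domain("`mask` must be a binary 0/1 matrix")
  out <- mask
  if (min_object_px > 0L && any(out == 1)) {
    lab <- label_components(out)
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < min_object_px)
    if (length(drop)) out[lab %in% drop] <- 0
  }
  if (fill_holes && any(out == 1)) {
    out <- (EBImage::fillHull(out) > 0) + 0
  }
  out
}

# Default minimum object size: the pixel count equivalent to `min_area_um2`
# at the image calibration.
default_min_object_px <- function(microns_per_pixel, min_area_um2 = 5) {
  max(1L, as.integer(ceiling(min_area_um2 / microns_per_pixel^2)))
}

#' Split confluent vacuoles with a marker-controlled watershed
#'
#' Runs the watershed transform on the negated Euclidean distance transform
#' of the mask. Markers are local maxima of the distance transform; maxima
#' closer together than `min_sep_px` are merged, so one convex blob yields
#' one region while touching vacuoles are split along the neck between them.
#' Every foreground pixel receives exactly one label (ridge pixels are
#' assigned to the adjacent basin), so the labels partition the mask.
#'
#' When `microns_per_pixel` and `cutoff_um2` are supplied and `min_sep_px` is
#' not, the minimum peak separation defaults to half the equivalent radius of
#' the smallest macrovesicle at the current calibration.
#'
#' @param mask binary `H x W` matrix.
#' @param min_sep_px minimum separation (in pixels) between watershed seeds.
#' @param microns_per_pixel,cutoff_um2 optional calibration used to derive
#'   `min_sep_px`.
#' @param tolerance minimum depth (in distance-transform units, i.e. pixels)
#'   separating two basins before they are kept distinct.
#' @return integer `H x W` label matrix (0 = background).
#' @export
watershed_separate <- function(mask, min_sep_px = NULL,
                               microns_per_pixel = NULL, cutoff_um2 = NULL,
                               tolerance = 1) {
  if (!is_binary_mask(mask)) stop_domain("`mask` must be a binary 0/1 matrix")
  if (!any(mask == 1)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (is.null(min_sep_px)) {
    min_sep_px <- if (!is.null(microns_per_pixel) && !is.null(cutoff_um2)) {
      r_eq <- sqrt(cutoff_um2 / pi) / microns_per_pixel
      max(1, r_eq / 2)
    } else 1
  }
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = tolerance,
                            ext = max(1L, as.integer(round(min_sep_px))))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

region_table <- function(label_image, microns_per_pixel, cutoff_um2) {
  ids <- seq_len(max(label_image, 0L))
  if (length(ids) == 0L)
    return(data.frame(id = integer(), area_px = integer(),
                      area_um2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), is_macro = logical()))
  fg <- which(label_image > 0L)
  labs <- label_image[fg]
  area_px <- tabulate(labs, nbins = max(ids))
  rows <- ((fg - 1L) %% nrow(label_image)) + 1L
  cols <- ((fg - 1L) %/% nrow(label_image)) + 1L
  crow <- rowsum(rows, labs)[, 1] / area_px
  ccol <- rowsum(cols, labs)[, 1] / area_px
  area_um2 <- area_px * microns_per_pixel^2
  data.frame(id = ids, area_px = area_px, area_um2 = area_um2,
             centroid_row = crow, centroid_col = ccol,
             is_macro = area_um2 >= cutoff_um2)
}

#' Quantify macrovesicular steatosis from a labeled vacuole image
#'
#' Flags every region whose physical area reaches `cutoff_um2` as a
#' macrovesicle and reports the ME percentage as macrovesicle pixel area over
#' total image area.
#'
#' @param label_image integer `H x W` label matrix (e.g. from
#'   [watershed_separate()]).
#' @param image the [calibrated_image] the mask came from (supplies the
#'   dimensions and microns-per-pixel scale).
#' @param cutoff_um2 macrovesicle area cutoff in um^2 (>= 0); see
#'   [macrovesicle_cutoff()].
#' @param tissue_only if `TRUE`, use only non-background tissue pixels
#'   (L* <= 95) as the denominator instead of the whole image.
#' @return object of class `steatosis_report`: `n_vacuoles`, `n_macro`,
#'   `fat_area_um2`, `macro_area_um2`, `me_percent`, `cutoff_um2`, and the
#'   per-region table `regions`.
#' @export
quantify_steatosis <- function(label_image, image, cutoff_um2,
                               tissue_only = FALSE) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!all(dim(label_image) == dim(image)))
    stop_domain("label image dimensions differ from image")
  if (cutoff_um2 < 0) stop_domain("cutoff_um2 must be >= 0")
  mpp <- image$microns_per_pixel
  regions <- region_table(label_image, mpp, cutoff_um2)
  macro_px <- sum(regions$area_px[regions$is_macro])
  denom_px <- if (tissue_only) {
    L <- rgb_to_cielab(image)$lab[, , 1]
    max(sum(L <= 95), 1L)
  } else length(label_image)
  structure(list(
    n_vacuoles = nrow(regions),
    n_macro = sum(regions$is_macro),
    fat_area_um2 = sum(regions$area_um2),
    macro_area_um2 = sum(regions$area_um2[regions$is_macro]),
    me_percent = 100 * macro_px / denom_px,
    cutoff_um2 = cutoff_um2,
    microns_per_pixel = mpp,
    regions = regions
  ), class = "steatosis_report")
}

#' @export
print.steatosis_report <- function(x, ...) {
  cat(sprintf("<steatosis_report> ME = %.2f%%\n", x$me_percent))
  cat(sprintf("  %d vacuoles (%d macrovesicular at cutoff %.2f um^2)\n",
              x$n_vacuoles, x$n_macro, x$cutoff_um2))
  cat(sprintf("  fat area %.1f um^2, macrovesicular %.1f um^2\n",
              x$fat_area_um2, x$macro_area_um2))
  invisible(x)
}

#' Write a steatosis report as JSON and one-row CSV
#' @param report a `steatosis_report`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "steatosis_report"))
  fields <- report[c("n_vacuoles", "n_macro", "fat_area_um2",
                     "macro_area_um2", "me_percent", "cutoff_um2")]
  if (!is.null(json_path))
    jsonlite::write_json(fields, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(fields), csv_path, row.names = FALSE)
  invisible(report)
}
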