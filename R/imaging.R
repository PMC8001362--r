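# Image I/O, spatial calibration, histogram matching, and color conversion.

#' Construct a calibrated image
#'
#' A calibrated image couples an 8-bit RGB raster with the physical size of a
#' pixel, derived from the camera sensor pitch and the acquisition
#' magnification:
#' \deqn{\mu m/px = sensor\_pixel\_size\_\mu m \times resize\_factor / magnification}
#'
#' @param pixels numeric `H x W x 3` array of 8-bit intensities in `[0, 255]`.
#' @param magnification positive scalar, the total optical magnification at
#'   acquisition (e.g. 100, 200, 400).
#' @param sensor_pixel_size_um physical sensor pixel pitch in microns
#'   (default 4.54, a common scientific CCD pitch).
#' @param resize_factor positive scalar; ratio between the stored image size
#'   and the native sensor frame, for images exported at reduced resolution.
#' @return an object of class `calibrated_image` with fields `pixels`,
#'   `magnification`, `sensor_pixel_size_um`, `resize_factor` and the derived
#'   `microns_per_pixel`.
#' @export
calibrated_image <- function(pixels, magnification,
                             sensor_pixel_size_um = 4.54,
                             resize_factor = 1.0) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_domain("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop_domain("image must have at least one row and one column")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_domain("channel values must lie in [0, 255]")
  assert_scalar_pos(magnification, "magnification")
  assert_scalar_pos(sensor_pixel_size_um, "sensor_pixel_size_um")
  assert_scalar_pos(resize_factor, "resize_factor")
  structure(list(
    pixels = pixels,
    magnification = magnification,
    sensor_pixel_size_um = sensor_pixel_size_um,
    resize_factor = resize_factor,
    microns_per_pixel = sensor_pixel_size_um * resize_factor / magnification
  ), class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %gx magnification, %.4g um/px\n",
              d[1], d[2], x$magnification, x$microns_per_pixel))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)[1:2]

read_raster <- function(path) {
  if (!file.exists(path)) stop_io("cannot read image: file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  res <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop_io("JPEG support requires the 'jpeg' package: %s", path)
      jpeg::readJPEG(path)
    },
    stop_io("unsupported image format '%s': %s", ext, path)
  ), error = function(e) {
    if (inherits(e, "steatoquant_error")) stop(e)
    stop_io("unreadable or corrupt image file %s (%s)", path, conditionMessage(e))
  })
  res
}

#' Load an image with spatial calibration
#'
#' Reads a PNG, TIFF, or JPEG raster and attaches the microns-per-pixel scale
#' derived from the acquisition magnification. Grayscale images are replicated
#' to three channels; an alpha channel is dropped.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @inheritParams calibrated_image
#' @return a [calibrated_image].
#' @export
load_image <- function(path, magnification,
                       sensor_pixel_size_um = 4.54, resize_factor = 1.0) {
  raw <- read_raster(path)
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  nc <- dim(raw)[3]
  px <- if (nc == 1L) {
    array(raw[, , 1L], c(dim(raw)[1:2], 3L))
  } else if (nc >= 3L) {
    raw[, , 1:3, drop = FALSE]
  } else stop_io("cannot interpret %d-channel image: %s", nc, path)
  calibrated_image(round(px * 255), magnification,
                   sensor_pixel_size_um, resize_factor)
}

# Per-channel 8-bit histogram-matching lookup table: for each input level the
# smallest reference level whose CDF reaches the input level's CDF.
match_lut <- function(src, ref) {
  cdf_s <- cumsum(tabulate(as.integer(src) + 1L, nbins = 256L)) / length(src)
  cdf_r <- cumsum(tabulate(as.integer(ref) + 1L, nbins = 256L)) / length(ref)
  lut <- integer(256L)
  for (v in 1:256) lut[v] <- which(cdf_r >= cdf_s[v] - 1e-9)[1] - 1L
  lut
}

#' Match an image's color histograms to a reference image
#'
#' Applies the classic per-channel histogram-matching algorithm: each RGB
#' channel is remapped through a monotone lookup table so that its empirical
#' intensity distribution approximates the reference channel's. Used to
#' normalize stain intensity variation across acquisitions before pixel
#' classification.
#'
#' @param image a [calibrated_image] to normalize.
#' @param reference a [calibrated_image] providing the target histograms.
#' @return a [calibrated_image] with the dimensions and calibration of
#'   `image` and remapped intensities.
#' @export
match_histogram <- function(image, reference) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(reference, "calibrated_image"))
  out <- image$pixels
  for (ch in 1:3) {
    lut <- match_lut(image$pixels[, , ch], reference$pixels[, , ch])
    out[, , ch] <- lut[as.integer(image$pixels[, , ch]) + 1L]
  }
  image$pixels <- out
  image
}

# Standard sRGB (IEC 61966-2-1) -> XYZ (D65/2 degrees) -> CIE L*a*b*.
# Implemented directly because the required reference path (sRGB primaries,
# D65 white, no chromatic re-adaptation) must be reproduced to 3 decimals.
srgb_to_lab_matrix <- function(rgb01) {
  u <- rgb01
  lin <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  wn <- as.vector(M %*% c(1, 1, 1))  # D65 white from the primaries themselves
  t3 <- sweep(xyz, 2, wn, "/")
  delta <- 6 / 29
  f <- ifelse(t3 > delta^3, t3^(1 / 3), t3 / (3 * delta^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' Convert a calibrated RGB image to CIE L*a*b*
#'
#' Uses the standard sRGB gamma and primaries with the D65/2-degree reference
#' white; `L*` is scaled 0-100.
#'
#' @param image a [calibrated_image].
#' @return an object of class `lab_image`: list with field `lab`, an
#'   `H x W x 3` array of `(L*, a*, b*)` values.
#' @export
rgb_to_cielab <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  d <- dim(image$pixels)
  m <- matrix(image$pixels, ncol = 3L) / 255
  lab <- srgb_to_lab_matrix(m)
  structure(list(lab = array(lab, d)), class = "lab_image")
}

#' @export
dim.lab_image <- function(x) dim(x$lab)[1:2]

#' Write a binary mask as a 0/255 single-channel PNG
#' @param mask binary `H x W` matrix (0/1).
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  if (!is_binary_mask(mask)) stop_domain("`mask` must be a binary 0/1 matrix")
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' Read a 0/255 mask PNG back to a binary matrix (threshold > 127)
#' @param path a single-channel (or RGB) mask PNG.
#' @return binary `H x W` matrix.
#' @export
read_mask_png <- function(path) {
  raw <- read_raster(path)
  if (!is.matrix(raw)) raw <- raw[, , 1L]
  (raw * 255 > 127) + 0L
}

#' Write a label image as 16-bit TIFF
#' @param label_image integer `H x W` matrix of region labels (0 = background).
#' @param path output path (.tif).
#' @export
write_label_tiff <- function(label_image, path) {
  if (max(label_image) > 65535L)
    stop_domain("more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(label_image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a QC overlay: mask contours drawn over the original image
#' @param image a [calibrated_image].
#' @param mask binary `H x W` matrix to outline.
#' @param path output PNG path.
#' @param color RGB triplet in 0-255 for the contour (default green).
#' @export
write_overlay_png <- function(image, mask, path, color = c(0, 255, 0)) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!all(dim(mask) == dim(image))) stop_domain("mask/image dimension mismatch")
  # boundary = mask pixels with at least one 4-neighbor outside the mask
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0L, h + 2L, w + 2L); pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  boundary <- mask == 1 & !inner
  out <- image$pixels
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[boundary] <- color[ch]
    out[, , ch] <- plane
  }
  png::writePNG(out / 255, path)
  invisible(path)
}
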