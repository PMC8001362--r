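# Synthetic Sudan-stained slide generator with pixel-exact ground truth.
# Emulates orange fat vacuoles on a pink-violet hematoxylin-counterstained
# background, plus the common acquisition artifacts (air bubbles, unstained
# blank spaces, dark unspecific deposits).

#' Specify a synthetic stained-slide image
#'
#' Defaults emulate a 1920 x 1080 export of a Sudan-stained frozen liver
#' section: near-round orange vacuoles (Gaussian color noise around an orange
#' mean) on a pink-violet counterstained background, with a 20% target fat
#' fraction unless a fixed `vacuole_count` is requested.
#'
#' @param dims image size `c(H, W)` in pixels.
#' @param magnification,sensor_pixel_size_um,resize_factor calibration passed
#'   to [calibrated_image()].
#' @param vacuole_count exact number of vacuoles to place, or `NULL` to place
#'   vacuoles until `fat_fraction` is reached.
#' @param fat_fraction target foreground fraction in `[0, 0.9)`; ignored when
#'   `vacuole_count` is given.
#' @param vacuole_radius_um `c(min, max)` vacuole semi-major axis in microns.
#' @param overlap_fraction proportion of vacuoles deliberately placed touching
#'   an earlier vacuole (confluent vacuoles for watershed testing).
#' @param vacuole_color,background_color lists with `mean` (RGB triplet,
#'   0-255) and `sd` (per-pixel Gaussian color noise).
#' @param artifacts list with counts `n_bubbles`, `n_blank_spaces`,
#'   `n_dark_deposits`; artifacts are always drawn outside the truth mask.
#' @param noise_sigma global additive Gaussian pixel noise (intensity units).
#' @param seed integer seed; generation is bit-reproducible.
#' @return object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(dims = c(1080L, 1920L),
                           magnification = 100,
                           sensor_pixel_size_um = 4.54,
                           resize_factor = 1.0,
                           vacuole_count = NULL,
                           fat_fraction = 0.2,
                           vacuole_radius_um = c(4, 15),
                           overlap_fraction = 0.15,
                           vacuole_color = list(mean = c(230, 140, 40), sd = 12),
                           background_color = list(mean = c(225, 185, 215), sd = 15),
                           artifacts = list(n_bubbles = 3L, n_blank_spaces = 2L,
                                            n_dark_deposits = 20L),
                           noise_sigma = 5,
                           seed = 0L) {
  if (length(dims) != 2L || any(dims < 1)) stop_domain("dims must be c(H, W) >= 1")
  if (is.null(vacuole_count)) {
    if (fat_fraction < 0) stop_domain("fat_fraction must be >= 0")
    if (fat_fraction > 0.9)
      stop_domain("infeasible packing: fat_fraction %.2f > 0.9", fat_fraction)
  } else if (vacuole_count < 0) stop_domain("vacuole_count must be >= 0")
  if (any(vacuole_radius_um <= 0)) stop_domain("vacuole radii must be positive")
  if (any(vacuole_color$mean < 0 | vacuole_color$mean > 255) ||
      any(background_color$mean < 0 | background_color$mean > 255))
    stop_domain("color means must lie in [0, 255]")
  if (any(unlist(artifacts) < 0)) stop_domain("artifact counts must be >= 0")
  structure(list(dims = as.integer(dims), magnification = magnification,
                 sensor_pixel_size_um = sensor_pixel_size_um,
                 resize_factor = resize_factor,
                 vacuole_count = vacuole_count, fat_fraction = fat_fraction,
                 vacuole_radius_um = vacuole_radius_um,
                 overlap_fraction = overlap_fraction,
                 vacuole_color = vacuole_color,
                 background_color = background_color,
                 artifacts = artifacts, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Linear indices of a filled rotated ellipse clipped to the image.
ellipse_indices <- function(H, W, cr, cc, a, b, theta) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(H, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(W, ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(integer())
  rs <- r0:r1; cs <- c0:c1
  dr <- rep(rs - cr, times = length(cs))
  dc <- rep(cs - cc, each = length(rs))
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  (rep(rs, times = length(cs)) + (rep(cs, each = length(rs)) - 1L) * H)[inside]
}

disc_indices <- function(H, W, cr, cc, r) ellipse_indices(H, W, cr, cc, r, r, 0)

paint <- function(img, idx, mean_rgb, sd) {
  if (!length(idx)) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- stats::rnorm(length(idx), mean_rgb[ch], sd)
    img[, , ch] <- plane
  }
  img
}

#' Generate a synthetic stained slide with ground truth
#'
#' Places filled elliptical vacuoles (axis ratio uniform in `[0.7, 1]`,
#' uniform rotation) until the target fat fraction or vacuole count is
#' reached, draws artifacts strictly outside the vacuole mask, then adds
#' Gaussian pixel noise and clips to `[0, 255]`.
#'
#' When a fat fraction is targeted, each new vacuole's nominal area is capped
#' by the remaining area budget, so the realized foreground fraction lands on
#' the target with sub-vacuole precision.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `image` (a [calibrated_image]), `truth_mask` (binary
#'   `H x W`; exactly the vacuole pixels), and `planted` (`data.frame` of each
#'   vacuole's center, axes, orientation, and true pixel/physical area).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$dims[1]; W <- spec$dims[2]
  mpp <- spec$sensor_pixel_size_um * spec$resize_factor / spec$magnification
  with_seed(spec$seed, {
    mask <- matrix(0L, H, W)
    planted <- list()
    r_px <- spec$vacuole_radius_um / mpp
    target_px <- if (is.null(spec$vacuole_count))
      as.integer(round(spec$fat_fraction * H * W)) else NA_integer_
    n_goal <- if (is.null(spec$vacuole_count)) Inf else spec$vacuole_count
    it <- 0L
    while (it < 50000L) {
      it <- it + 1L
      if (is.null(spec$vacuole_count)) {
        remaining <- target_px - sum(mask)
        if (remaining <= 0L) break
      } else if (length(planted) >= n_goal) break
      a <- stats::runif(1, r_px[1], r_px[2])
      if (is.null(spec$vacuole_count)) {
        # cap the nominal area by the remaining budget so the realized
        # fraction lands near the target, but never below the requested
        # radius range minimum: the range is a hard contract (e.g. all
        # vacuoles macrovesicular), so the final vacuole may overshoot by
        # at most one minimum-size vacuole
        a <- max(min(a, sqrt(remaining / pi)), r_px[1], 2)
      }
      ratio <- stats::runif(1, 0.7, 1)
      b <- a * ratio
      theta <- stats::runif(1, 0, pi)
      if (length(planted) && stats::runif(1) < spec$overlap_fraction) {
        anchor <- planted[[sample.int(length(planted), 1L)]]
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 0.5, 0.9) * (anchor$a_px + a)
        cr <- anchor$centroid_row + d * cos(ang)
        cc <- anchor$centroid_col + d * sin(ang)
      } else {
        cr <- stats::runif(1, 1, H)
        cc <- stats::runif(1, 1, W)
      }
      idx <- ellipse_indices(H, W, cr, cc, a, b, theta)
      if (length(idx) < 4L) next
      mask[idx] <- 1L
      planted[[length(planted) + 1L]] <- list(
        centroid_row = cr, centroid_col = cc, a_px = a, b_px = b,
        theta = theta, area_px = length(idx))
    }
    img <- array(0, c(H, W, 3))
    img <- paint(img, seq_len(H * W), spec$background_color$mean,
                 spec$background_color$sd)
    # artifacts: drawn only where there is no vacuole
    bg_only <- function(idx) idx[mask[idx] == 0L]
    for (i in seq_len(spec$artifacts$n_bubbles)) {
      r <- stats::runif(1, 0.02, 0.05) * min(H, W)
      cr <- stats::runif(1, 1, H); cc <- stats::runif(1, 1, W)
      outer <- disc_indices(H, W, cr, cc, r)
      inner <- disc_indices(H, W, cr, cc, max(r - 2, 1))
      img <- paint(img, bg_only(inner), c(248, 246, 240), 3)
      img <- paint(img, bg_only(setdiff(outer, inner)), c(90, 85, 80), 5)
    }
    for (i in seq_len(spec$artifacts$n_blank_spaces)) {
      cr <- stats::runif(1, 1, H); cc <- stats::runif(1, 1, W)
      idx <- integer()
      for (j in 1:4) {
        r <- stats::runif(1, 0.01, 0.03) * min(H, W)
        idx <- c(idx, disc_indices(H, W, cr, cc, r))
        cr <- cr + stats::rnorm(1, 0, r); cc <- cc + stats::rnorm(1, 0, r)
      }
      img <- paint(img, bg_only(unique(idx)), c(242, 240, 244), 3)
    }
    for (i in seq_len(spec$artifacts$n_dark_deposits)) {
      idx <- disc_indices(H, W, stats::runif(1, 1, H), stats::runif(1, 1, W),
                          stats::runif(1, 1, 3))
      img <- paint(img, bg_only(idx), c(75, 45, 95), 8)
    }
    # vacuoles on top
    fg <- which(mask == 1L)
    img <- paint(img, fg, spec$vacuole_color$mean, spec$vacuole_color$sd)
    if (spec$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma), dim(img))
    img <- pmin(pmax(round(img), 0), 255)
    planted_df <- if (length(planted)) {
      df <- do.call(rbind, lapply(planted, as.data.frame))
      df$id <- seq_len(nrow(df))
      df$area_um2 <- df$area_px * mpp^2
      df[, c("id", "centroid_row", "centroid_col", "a_px", "b_px", "theta",
             "area_px", "area_um2")]
    } else data.frame(id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), a_px = numeric(),
                      b_px = numeric(), theta = numeric(),
                      area_px = integer(), area_um2 = numeric())
    list(image = calibrated_image(img, spec$magnification,
                                  spec$sensor_pixel_size_um,
                                  spec$resize_factor),
         truth_mask = mask, planted = planted_df)
  })
}

#' Default histogram-matching reference image
#'
#' A synthetic stained slide generated with fixed seed 0, used as the packaged
#' reference for [match_histogram()] when the user supplies none.
#'
#' @param dims image size; the default is small because only the channel
#'   histograms matter.
#' @return a [calibrated_image].
#' @export
default_reference_image <- function(dims = c(256L, 256L)) {
  generate_slide(synthetic_spec(dims = dims, magnification = 20, seed = 0L))$image
}

#' Sample class-pure labeled windows from a ground-truth mask
#'
#' Draws, for each requested window size, half the windows entirely inside
#' vacuoles (label 1) and half entirely outside (label 0), using an integral
#' image to enumerate all class-pure placements. The default request mirrors
#' the manual protocol: 10 windows of 50x50, 10 of 100x100, 50 of 20x20 and
#' 50 of 10x10 (150,000 pixels in total).
#'
#' @param image a [calibrated_image] (supplies the dimensions and image id).
#' @param truth_mask binary ground-truth mask.
#' @param n_per_size windows to draw per size (same length as `sizes`).
#' @param sizes square window sides, in pixels.
#' @param seed integer seed.
#' @param image_id identifier recorded in the windows table.
#' @return windows `data.frame` (`image_id,row,col,height,width,label`,
#'   0-based origins). If a class has too few pure placements for a size, the
#'   shortfall is dropped with a warning.
#' @export
generate_labeled_windows <- function(image, truth_mask,
                                     n_per_size = c(10L, 10L, 50L, 50L),
                                     sizes = c(50L, 100L, 20L, 10L),
                                     seed = 0L, image_id = "synthetic") {
  stopifnot(length(n_per_size) == length(sizes))
  H <- nrow(truth_mask); W <- ncol(truth_mask)
  # padded integral image of the mask
  S <- matrix(0, H + 1L, W + 1L)
  S[-1, -1] <- t(apply(apply(truth_mask, 2, cumsum), 1, cumsum))
  out <- list()
  with_seed(seed, {
    for (i in seq_along(sizes)) {
      s <- sizes[i]; n <- n_per_size[i]
      if (n == 0L || s > H || s > W) {
        if (n > 0L) warning(sprintf("window size %d exceeds image; skipped", s))
        next
      }
      nr <- H - s + 1L; nc <- W - s + 1L
      sums <- S[(1L + s):(H + 1L), (1L + s):(W + 1L)] -
        S[1:nr, (1L + s):(W + 1L)] - S[(1L + s):(H + 1L), 1:nc] + S[1:nr, 1:nc]
      pure1 <- which(sums == s * s)
      pure0 <- which(sums == 0)
      want <- c(`1` = ceiling(n / 2), `0` = floor(n / 2))
      for (cl in c("1", "0")) {
        pool <- if (cl == "1") pure1 else pure0
        k <- min(want[[cl]], length(pool))
        if (k < want[[cl]])
          warning(sprintf("only %d pure class-%s windows of size %d available (wanted %d)",
                          k, cl, s, want[[cl]]))
        if (k == 0L) next
        pick <- pool[sample.int(length(pool), k)]
        r0 <- ((pick - 1L) %% nr)          # 0-based origins
        c0 <- ((pick - 1L) %/% nr)
        out[[length(out) + 1L]] <- data.frame(
          image_id = image_id, row = r0, col = c0, height = s, width = s,
          label = as.integer(cl), stringsAsFactors = FALSE)
      }
    }
  })
  if (!length(out))
    return(data.frame(image_id = character(), row = integer(), col = integer(),
                      height = integer(), width = integer(), label = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
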