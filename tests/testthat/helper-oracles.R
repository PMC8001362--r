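# Independent oracles, deliberately coded differently from the package paths.

# Scalar-loop sRGB -> Lab (D65/2deg) closed form.
oracle_srgb_to_lab <- function(r, g, b) {
  gam <- function(u) if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  rl <- gam(r / 255); gl <- gam(g / 255); bl <- gam(b / 255)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(X / 0.95047); fy <- f(Y / 1); fz <- f(Z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Inverse closed form Lab -> sRGB, for round-trip checks.
oracle_lab_to_srgb <- function(L, a, b) {
  fy <- (L + 16) / 116; fx <- fy + a / 500; fz <- fy - b / 200
  finv <- function(f) if (f > 6 / 29) f^3 else 3 * (6 / 29)^2 * (f - 4 / 29)
  X <- 0.95047 * finv(fx); Y <- finv(fy); Z <- 1.08883 * finv(fz)
  rl <- 3.2404542 * X - 1.5371385 * Y - 0.4985314 * Z
  gl <- -0.9692660 * X + 1.8760108 * Y + 0.0415560 * Z
  bl <- 0.0556434 * X - 0.2040259 * Y + 1.0572252 * Z
  gaminv <- function(u) {
    u <- max(0, min(1, u))
    if (u <= 0.0031308) 12.92 * u else 1.055 * u^(1 / 2.4) - 0.055
  }
  255 * c(gaminv(rl), gaminv(gl), gaminv(bl))
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2).
oracle_auc_pairs <- function(score, labels) {
  pos <- score[labels == 1]; neg <- score[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Brute-force per-pixel confusion counting.
oracle_confusion <- function(auto, manual) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(auto)) {
    if (auto[i] == 1 && manual[i] == 1) tp <- tp + 1L
    else if (auto[i] == 1 && manual[i] == 0) fp <- fp + 1L
    else if (auto[i] == 0 && manual[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Hole filling by queue-based flood fill of the background from the border;
# unreachable background pixels are holes.
oracle_fill_holes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  reach <- matrix(FALSE, H, W)
  queue <- c(which(mask[1, ] == 0) * H - H + 1L,            # row 1
             which(mask[H, ] == 0) * H,                      # row H
             which(mask[, 1] == 0),                          # col 1
             (W - 1L) * H + which(mask[, W] == 0))           # col W
  queue <- unique(queue)
  reach[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    r <- (i - 1L) %% H + 1L; cc <- (i - 1L) %/% H + 1L
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nr <- r + d[1]; nc <- cc + d[2]
      if (nr < 1 || nr > H || nc < 1 || nc > W) next
      j <- nr + (nc - 1L) * H
      if (!reach[j] && mask[j] == 0) {
        reach[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  out <- mask
  out[mask == 0 & !reach] <- 1
  out
}

# Well-separated two-class six-channel color table (fixture, not an oracle):
# orange-ish class 1 vs violet-ish class 0.
make_separable_table <- function(n, seed = 1, sd = 8) {
  set.seed(seed)
  n1 <- n %/% 2; n0 <- n - n1
  mu1 <- c(230, 140, 40, 65, 30, 60)
  mu0 <- c(225, 185, 215, 80, 20, -15)
  f1 <- sweep(matrix(rnorm(n1 * 6, 0, sd), n1, 6), 2, mu1, "+")
  f0 <- sweep(matrix(rnorm(n0 * 6, 0, sd), n0, 6), 2, mu0, "+")
  feats <- rbind(f1, f0)
  feats[, 1:3] <- pmin(pmax(feats[, 1:3], 0), 255)
  feature_table(feats, c(rep(1L, n1), rep(0L, n0)))
}

# Small synthetic slide used across tests: magnification 20 so the default
# micron-scale vacuoles span tens of pixels.
make_slide <- function(seed = 42, fraction = 0.2, dims = c(240L, 320L),
                       radius_um = c(4, 10), overlap = 0.15) {
  generate_slide(synthetic_spec(
    dims = dims, magnification = 20, fat_fraction = fraction,
    vacuole_radius_um = radius_um, overlap_fraction = overlap, seed = seed))
}

# Slide whose vacuoles are all comfortably macrovesicular (>= 146.71 um^2)
# at a calibration fine enough for sub-point fat-fraction control.
make_macro_slide <- function(seed, fraction, dims = c(320L, 440L)) {
  generate_slide(synthetic_spec(
    dims = dims, magnification = 10, fat_fraction = fraction,
    vacuole_radius_um = c(10, 16), seed = seed))
}

# Training table sampled from a slide's pure windows.
slide_training_table <- function(slide, n_pixels = 10000L, seed = 7L) {
  lab <- rgb_to_cielab(slide$image)
  w <- generate_labeled_windows(slide$image, slide$truth_mask,
                                n_per_size = c(20L, 60L), sizes = c(20L, 10L),
                                seed = seed)
  tab <- extract_windows(slide$image, lab, w)
  subsample_features(tab, min(n_pixels, tab$n), seed = seed)
}

# A tiny temporary RGB PNG for I/O tests.
write_tmp_png <- function(px01, ext = ".png") {
  f <- tempfile(fileext = ext)
  png::writePNG(px01, f)
  f
}
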