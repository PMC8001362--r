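---
title: "Quantifying macrovesicular steatosis in Sudan-stained liver sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macrovesicular steatosis in Sudan-stained liver sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Macrovesicular steatosis (ME) — hepatocyte fat stored as one large droplet
that displaces the nucleus — is a key quality parameter when a donor liver is
evaluated for transplantation, and it must be assessed on frozen sections
within minutes. Sudan staining renders lipid orange while a hematoxylin
counterstain colors the remaining tissue pink-violet, so on these slides fat
is separable from everything else **by pixel color alone**. steatoquant
implements that idea as a complete measurement pipeline:

1. calibrate the image (microns per pixel from the acquisition
   magnification),
2. optionally normalize staining with histogram matching to a reference
   image,
3. classify every pixel as fat vacuole / non-vacuole from its six-channel
   color vector,
4. clean the binary mask and split confluent vacuoles with a watershed,
5. keep vacuoles at least twice the size of a normal hepatocyte nucleus
   (the macrovesicle size rule), and
6. report ME as the percentage of the image covered by macrovesicles.

## Spatial calibration and the macrovesicle cutoff

Physical pixel size is derived from the camera sensor pitch (default
4.54 µm, a common scientific CCD) as

    microns_per_pixel = sensor_pixel_size_um * resize_factor / magnification.

`resize_factor` accommodates images exported at a different resolution than
the native sensor frame; it is exposed rather than guessed because exported
image sizes vary between acquisition setups.

Histology defines a macrovesicle as a vacuole at least twice the size of a
normal hepatocyte nucleus. With the reference mean nuclear area of
73.356 µm² measured on hematoxylin-stained frozen liver sections, the
default area cutoff is

```{r}
library(steatoquant)
macrovesicle_cutoff(73.356)
```

µm², and any region at or above it counts toward the ME percentage. The ME
denominator is the total image area by default; a tissue-only denominator
(excluding near-white background with an L* > 95 rule) is available behind
the `tissue_only` flag, since protocols differ on background exclusion.

## Color features and the pixel classifiers

Every pixel contributes a six-channel feature vector
\((R, G, B, L^*, a^*, b^*)\): the raw 8-bit sRGB intensities plus the CIE
L\*a\*b\* coordinates computed with the standard sRGB gamma and primaries
under the D65/2° reference white (L\* scaled 0–100). The Lab conversion is
implemented directly from the closed form; the reference white is taken as
the row sums of the sRGB→XYZ matrix so that pure white maps to exactly
L\* = 100, a\* = b\* = 0 and L\* never exceeds 100 by rounding.

Training data come from small class-pure rectangular windows placed entirely
inside or entirely outside vacuoles. Only the 70/30 train/test split is
stratified (per-class counts are rounded half up); pixel-budget subsampling
is plain uniform sampling without replacement. Every stochastic operation
takes an explicit integer seed and restores the caller's RNG state.

Six classifiers are exposed behind one interface, with pinned defaults so
behavior does not depend on library versions:

| id | model | pinned defaults |
|---|---|---|
| `knn` | k-nearest neighbors | k = 5, Euclidean; all equidistant neighbors at the boundary vote (deterministic ties) |
| `svm` | RBF support vector machine | C = 1, gamma = 1/(6 · feature variance), no internal rescaling |
| `rf` | random forest | 100 trees, Gini, 2 features per split |
| `nb` | Gaussian naive Bayes | per-class Gaussian likelihoods |
| `nn` | one-hidden-layer network | 100 ReLU units, Adam (lr 0.001), 100 epochs, batch 256 |
| `dense-nn` | minimal dense network | 6 sigmoid units → 2 softmax units, Adamax (lr 0.002), cross-entropy, 100 epochs, batch 256 |

Features are fed **unscaled** (a standardization switch exists but defaults
off). The two neural networks share a small built-in engine (forward pass,
backpropagation, Adam/Adamax); the `dense-nn` architecture is fixed at
6 → 6 → 2, i.e. exactly 56 trainable weights. Because the raw features span
0–255, initial weights are drawn from N(0, 0.01): large enough to break
symmetry, small enough to keep the sigmoid units out of saturation at the
first forward pass. Cross-entropy is used as the loss, the only standard
pairing with a softmax output. Training length (100 epochs, batch 256) is a
fixed, documented choice with early stopping disabled, so runs are exactly
reproducible from the seed.

Whole-image classification partitions the image into contiguous row blocks
processed independently and reassembled in order, so the predicted mask is
bit-identical for every thread count. Hard class decisions are the argmax of
the class scores with exact ties resolved to the non-vacuole class.

Evaluation computes the ROC curve from the continuous class-1 scores and its
area by the trapezoid rule with tied scores grouped, which equals the
normalized Mann–Whitney U statistic (ties counted 1/2).

## Histogram matching

Stain intensity varies between acquisitions, so an image can be normalized
to a reference before classification. Matching is the classic per-channel
monotone remap: for each RGB channel and each 8-bit level, the output level
is the smallest reference level whose empirical CDF reaches the input
level's CDF. Per-channel (marginal) matching is used — the standard
match-histogram algorithm — rather than any joint-distribution transfer.
Matching an image to itself is the identity, and re-matching an already
matched image changes pixels by at most one intensity step. The packaged
default reference is a synthetic slide generated with fixed seed 0, for use
when no laboratory reference is supplied.

## Watershed separation of confluent vacuoles

Touching vacuoles must be counted and sized as separate objects. The binary
mask is first cleaned: 8-connected components smaller than the pixel
equivalent of 5 µm² are removed and interior holes are filled. The watershed
transform then runs on the negated Euclidean distance transform of the
mask. Markers are local maxima of the distance transform; maxima closer than
a minimum separation are merged, where the default separation is **half the
equivalent radius of the smallest macrovesicle** at the current calibration
(computed from the area cutoff and microns-per-pixel). This is the standard
cell-splitting recipe: one convex blob keeps a single marker, while two
overlapping discs keep two. Ridge pixels are assigned to an adjacent basin,
so the labels exactly partition the mask foreground — no fat pixel is lost
or double-counted. Region connectivity is 8-neighbor throughout.

## The synthetic slide generator

No stained-slide dataset ships with the package; instead a generator
produces images that emulate the relevant structure of Sudan-stained
sections with pixel-exact ground truth:

* **vacuoles** — filled ellipses (axis ratio uniform in [0.7, 1], uniform
  rotation, near-round as in liver histology) with per-pixel Gaussian color
  noise around an orange mean (230, 140, 40), σ = 12;
* **background** — pink-violet counterstain color (225, 185, 215), σ = 15;
* **artifacts** — air bubbles (near-white discs with dark rims), unstained
  blank spaces (irregular near-white blobs), and small dark-violet
  deposits, always drawn outside the vacuole mask;
* global Gaussian pixel noise (σ = 5) added last, then clipped to [0, 255].

The color means and spreads are a fixed documented palette chosen to look
like the stain combination; no published color statistics exist for these
preparations, so the palette is the package's own calibration of "clearly
stained" material. Defaults target a 1920 × 1080 frame, a 20% fat fraction,
and 4–15 µm vacuole radii.

When a fat fraction is targeted, ellipses are added until the foreground
reaches the target; each new ellipse's nominal area is capped by the
remaining budget so the realized fraction lands on the target with
sub-vacuole precision. The cap never shrinks a vacuole below the requested
radius-range minimum — the range is a hard contract, so for instance a range
of 10–16 µm guarantees every planted vacuole is macrovesicular — at the cost
of a final overshoot of at most one minimum-size vacuole. Overlapping
vacuoles are unioned in the truth mask but recorded individually, so
watershed splitting can be scored. Requested fat fractions above 0.9 are
rejected as infeasible packing.

Class-pure training windows are sampled from the ground truth with an
integral image enumerating every placement whose pixels are all inside (or
all outside) the mask; the default request reproduces the manual protocol of
10 windows of 50×50, 10 of 100×100, 50 of 20×20 and 50 of 10×10 — 120
windows and 150,000 pixels. (The window counts define that pixel total by
arithmetic; requests that cannot be satisfied class-purely return fewer
windows with a warning.)

**What the generator does not emulate:** real tissue texture, nuclei,
sinusoids, chromatic aberration, uneven illumination, or compression
artifacts. Passing tests on synthetic slides therefore demonstrates that the
measurement machinery is correct — calibration, classification given
separable colors, watershed accounting, ME arithmetic — not that any
particular classifier will reach the same accuracy on real material, where
color overlap between stains is larger and artifact colors are less
stereotyped.

## Numerical choices

* The cutoff doubling is rounded half up to 2 decimals (73.356 → 146.71).
* Stratified splits round per-class train counts half up; train and test
  index sets partition the input exactly.
* Score ties at the decision threshold go to the non-vacuole class; AUC
  counts tied score pairs 1/2.
* `microns_per_pixel` is linear in 1/magnification, so doubling the
  magnification halves it exactly; ME percentages are scale-free while
  physical areas scale with the calibration squared.
* Metric ratios with zero denominators are reported as `NA` (undefined),
  never coerced to a number; an all-zero confusion table is an error.
* Watershed basin-depth tolerance is 1 px of distance-transform height.

Test and example problem sizes are deliberately moderate — slides of
roughly 240 × 320 to 320 × 440 pixels at calibrations of 0.23–0.45 µm/px,
training budgets of 10,000 pixels — chosen so the full property suite
exercises every stage (including 25 end-to-end pipeline runs across planted
fractions 5–50%) in a few minutes while keeping every vacuole tens of
pixels across, the same geometric regime as the default 1920 × 1080 frame.

## Known limitations

* At extreme infiltration (70–80% fat with heavy confluence), watershed
  under-segments very large merged vacuole complexes, so the vacuole
  *count* is unreliable there; the ME *percentage* is largely unaffected
  because the merged complexes are far above the cutoff either way. The
  generator can produce this regime so the limitation is reproducible.
* The macrovesicle rule is operationalized purely by size; nuclear
  displacement is not detected (the pipeline never sees nuclei).
* Microvesicular steatosis is not graded.
* Whole-slide pyramidal images are out of scope; inputs are single
  camera frames.
* Windows are labeled per-window, not per-pixel: a window straddling a
  vacuole boundary contaminates training. When a ground-truth mask is
  available the extractor warns if more than 5% of a window's pixels
  disagree with its label.
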