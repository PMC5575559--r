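---
title: "Methods: quantifying adherent cell growth on microcarriers from epi-illumination images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying adherent cell growth on microcarriers from epi-illumination images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierscope)
```

## The measurement problem

Anchorage-dependent cells such as mesenchymal stem cells are expanded at
scale on microcarriers — spherical beads of roughly 100–300 µm diameter
suspended in stirred culture. The standard ways of measuring how such a
culture is doing (sampling, enzymatic detachment, nuclear staining and
counting) are invasive, destroy the sample, and cannot drive automated
feedback. An in-situ epi-illumination microscope can instead image
colonized carriers directly in the vessel: cells appear as the brightest
structures on the illuminated upper hemisphere of each carrier, the
carrier body is mid-gray, and the background is dark and nearly uniform.

`carrierscope` implements the image-analysis half of that measurement
chain: given 8-bit grayscale frames it estimates per-carrier confluence,
counts cells per carrier, flags carrier aggregates, and assembles
culture-level growth statistics. Everything is validated against a
synthetic scene renderer whose ground truth is known by construction.

All intensities are kept on the 8-bit `[0, 255]` scale regardless of
source bit depth, because the classical thresholds of this method
(e.g. the constant segmentation threshold 0.4 × 21.1) are stated in
8-bit units. Pixel coordinates are 0-based `(row, col)` with the origin
at the top-left; circle centers may be fractional. The default physical
scale, 0.467 µm/px, is the ratio of a 598 µm field of view to 1280
detector pixels, and is overridable in the configuration.

## Confluence from local intensity variability

The background of an epi-illumination frame varies very little from
pixel to pixel, whereas cell-covered regions are strongly textured. The
segmentation statistic is therefore a *windowed standard deviation*: a
15 × 15 px window slides across the image with 93% overlap in both
directions (for the default kernel that is a stride of one pixel,
`max(1, round(15 × 0.07)) = 1`), and each window's population standard
deviation is credited to every pixel the window covers. Where windows
overlap, a pixel keeps the *maximum* — a pixel is foreground if any
neighborhood it belongs to is variable enough. A pixel is classified as
cell when this statistic reaches a threshold, and confluence is simply
the percentage of pixels classified as cell.

Two thresholding modes exist:

* **adaptive** (default): threshold = 0.35 × σ~image~, where σ~image~ is
  the grayscale standard deviation of the analyzed image (or, for
  per-carrier confluence, of the in-circle pixels only). The threshold
  scales with image contrast, which is what makes dark or washed-out
  frames measurable at all.
* **constant**: a fixed threshold (default 8.44 = 0.4 × 21.1, a
  reference value for monolayer flask images). This mode exists for
  comparison; it is known to fail on dark, near-confluent images.

Design choices a maintainer should know about:

* The window statistic is the *population* standard deviation (divisor
  n). On flat windows both conventions give 0; the population form
  avoids an arbitrary n−1 on the tiny-n masked windows at carrier rims.
* The combination rule over overlapping windows is *any window passes*
  (max-accumulation). This retains whole regions of high variability
  rather than only window centers, at the cost of a known one-sided
  boundary band: pixels up to about one kernel width outside a textured
  region can be claimed by a window that still overlaps the texture. On
  region boundaries the band is roughly 3–14 px depending on contrast;
  it is the dominant error source of the method and the reason the
  accuracy statements below are tied to feature sizes much larger than
  the kernel.
* The default factor is 0.35, the value used for microcarrier analysis;
  0.40 (used historically for flask monolayers) is one configuration
  key away. Neither is hard-coded.
* Windows are fully interior — no padding is invented at image borders.
  With a stride above one, pixels beyond the last full window inherit
  the nearest covered pixel's value.
* A featureless image (σ~image~ = 0) would make the adaptive threshold
  0 and classify everything as cell; this degenerate case is caught and
  reported as 0% confluence with a warning.
* For per-carrier confluence, window statistics are computed from the
  in-circle pixels each window covers (masked statistics), so the dark
  surround neither dilutes σ~image~ nor leaks variability across the
  rim.

## Carrier detection and isolation

Carriers are near-perfect circles, so they are found with a circular
Hough transform. Pixels whose Sobel gradient magnitude exceeds the 90th
percentile of nonzero gradients vote, for each candidate radius, at the
two points lying that radius away along their gradient direction
(capped at the 20 000 strongest edges). Accumulator peaks, normalized
by circumference, are circle hypotheses; greedy non-maximum suppression
enforces a minimum center separation (default 1.2 × the minimum search
radius, so one carrier cannot yield two hits), and center and radius
are then refined from the supporting votes and edge pixels. Ties are
broken by smaller row, then column, then radius, making detection fully
deterministic. The default radius search range, 139–268 px, is the
Cytodex-class diameter range (~130–250 µm) divided by the default pixel
scale.

`crop_to_circle()` extracts a carrier's bounding box plus the in-circle
mask; the cell counter and the per-carrier confluence both operate on
that crop.

## Cell counting on a carrier

Cells are compact bright blobs, so the detector is a
Laplacian-of-Gaussian filter with the sign convention that bright blobs
give positive peaks, mean-corrected to zero response on flat input, and
applied under mirror border padding. The pipeline on a carrier crop is,
in order: (1) LoG filter; (2) a grayscale gate that zeroes the response
wherever the *raw* intensity is below `cell_intensity_threshold`
(default 200) — cells are the brightest structures, and gating after
filtering avoids manufacturing artificial edges; (3) binarization of
the remaining response at a fraction (default 0.2) of its maximum;
(4) 8-connected component labeling; (5) area filtering
(default 40–2000 px²) and the requirement that the component centroid
lies inside the carrier mask.

The LoG scale was tuned in the original method without a published
value; the package derives it from geometry instead:
σ = (10 µm / pixel scale) / √2 ≈ 15 px for a ~10 µm cell radius, with
kernel size 2⌈3σ⌉+1. Both are configuration keys.

The visible count is finally doubled (`hemisphere_corrected_count()`),
under the assumption that only the illuminated upper hemisphere is
counted and the hidden hemisphere carries as many cells again.
Multiplying the mean corrected count per carrier by the carrier
concentration (`cell_density()`) puts the measurement on a cells/mL
axis comparable with off-line nuclear counts.

Known limitation, by design: overlapping cells that fuse into one
component are counted once — there is no watershed splitting. On dense,
late-culture carriers the method therefore undercounts, which is
consistent with how this family of methods behaves once aggregation
starts.

## Aggregate detection

Aggregated carriers impair nutrient transfer and break the
one-carrier-per-image assumption, so frames containing clumps are
flagged: binarize (Otsu's threshold by default, a fixed value
optionally), dilate with a disk (default radius 5 px) so each carrier's
bright regions agglomerate into one object, label 8-connected
components, and keep components that are carrier-sized
(default 30 000–150 000 px²) and near-circular (equivalent-ellipse
eccentricity ≤ 0.8). An image is flagged when *more than two* such
objects are present — the strict reading of the rule, i.e. at least
three. The alternative reading (any multi-carrier clump, ≥ 2) is one
configuration change away, as is an optional extension that also flags
a single over-sized component (carriers fused into one object), which
is off by default to keep the flag rule exact. `aggregate_rate()`
converts flags into aggregates per 50 images, overall or per culture
day.

## Culture-level statistics

`running_mean()` and `convergence_index()` quantify how many carriers
must be imaged before the per-carrier mean stabilizes: the convergence
index is the first position from which every partial mean stays within
a tolerance band (default ±5%) of the final mean — chosen as an
explicit criterion for what is usually judged by eye; with ~30 cells
per carrier it typically lands at a few dozen carriers, matching
practical experience. When the final mean is zero the band degenerates
to an absolute ±tolerance. `colonization_histogram()` bins per-carrier
counts (default bin width 5 cells) and normalizes to the day's maximum
bin, so colonization distributions of days with very different numbers
of analyzed carriers remain comparable; `build_growth_profile()`
assembles the day-by-day growth curve, reporting days with no
analyzable carriers as missing rather than zero (aggregation can make
carriers undetectable, and a zero would be a false measurement).

## The synthetic scene renderer

No public image set exists for this instrument class, so validation
rests on `render_scene()` / `render_monolayer()` / `render_suite()`,
which generate images *with ground truth*: carriers as shaded disks
with a brighter rim (soft logistic edge, rim bump just inside the
nominal radius), cells as additive Gaussian blobs (default σ 10 px,
amplitude 110 over the body — FWHM ≈ 11 µm at the default pixel scale),
optional in-carrier confluent texture, and i.i.d. Gaussian sensor noise
added last, everything clamped to [0, 255]. Monolayers are rendered by
thresholding a bilinearly upsampled coarse Gaussian field at the
empirical quantile of the target coverage (patch scale 320 px —
confluent colonies span hundreds of pixels), filling the region with
zero-mean texture (σ 45) whose amplitude ramps up quadratically over
16 px from the colony border, emulating the sparse fringe of edge
cells, plus σ = 2 sensor noise everywhere. The realized coverage is
recorded exactly in the truth object.

Randomness uses R's Mersenne-Twister with inversion normals under a
per-scene seed (suite scene *i* samples parameters under
`seed + i − 1` and renders under that value + 10⁶), and the caller's
RNG state is restored afterwards, so every scene is bit-reproducible.

What the renderer does *not* emulate — and hence what passing tests do
not show about real data: optical physics (defocus, interference
fringes, vignetting, halos), motion blur of moving carriers,
non-Gaussian sensor noise, cell morphology and brightness
heterogeneity, debris, and carriers touching so closely that their
bright bodies merge into one binarized object. Results on synthetic
suites bound algorithmic correctness, not instrument performance.

Problem sizes used by the validation suites, chosen to exercise the
geometry at realistic scale: monolayers 768 × 768 px; single-carrier
scenes 520 × 520 px with radii 150–235 px (200–235 px for the dense
counting suites, where up to 40 cells at realistic spacing must fit on
one projected hemisphere); pair/aggregate scenes on the full
1024 × 1280 px detector frame with radii 140–180 px and edge-to-edge
gaps of 15–30 px. In aggregate scenes carriers are closely spaced but
keep visible interstices, as real clumped carriers keep separate bright
bodies; fully fused bright regions are the documented blind spot of the
object-count rule (see the optional merged-component extension above).

## Numerical choices

* Window sums for the std map use shifted additions (k adds per axis),
  not integral images, keeping the agreement with an exhaustive
  per-window oracle at the 10⁻⁹ level on 8-bit data.
* Max-accumulation over covering windows is a separable left-looking
  running maximum, O(kN).
* LoG convolution is FFT-based on a mirror-padded image; the dense
  brute-force convolution agrees to 10⁻⁶.
* Component labeling wraps a 4-connected labeler and merges diagonal
  neighbors with union–find, giving true 8-connectivity; labels are
  renumbered deterministically by first pixel.
* Eccentricity is the equivalent-ellipse definition from second-order
  central moments; degenerate single-pixel components report 0.
* Degenerate inputs have defined behavior throughout: featureless
  images → 0% confluence with a warning; no circle above the minimum
  Hough score → empty result, not an error; an empty detection set is a
  valid cell count of zero; an empty group in rate computation reports
  `NA`.

## A worked example

```{r example, eval = FALSE}
library(carrierscope)

# a colonized carrier with 12 cells, rendered with ground truth
sc <- render_suite("single-carrier", 1, seed = 51, n_cells = 12)[[1]]

rec <- analyze_image(sc$image, image_id = "demo", culture_day = 4L)
rec$carriers[, c("radius_px", "confluence_pct",
                 "cells_visible", "cells_corrected")]

# culture statistics from per-carrier counts
counts <- c(18, 22, 30, 26, 24, 28, 30, 26)
convergence_index(running_mean(counts))
colonization_histogram(counts, bin_width = 5)
```

The same operations are reachable from the shell through the installed
`exec/carrierscope` script (`simulate`, `confluence`, `carriers`,
`count`, `aggregates`, `growth`), each subcommand a thin wrapper over
the functions above.
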