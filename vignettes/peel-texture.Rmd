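---
title: "Peel roughness and the R-LBP encoding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peel roughness and the R-LBP encoding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlbp)
```

This vignette documents the models implemented by **rlbp**, the parameters
that matter, the numerical conventions, and the design choices that were
genuinely open — so that a reader can judge what the package computes and
what its synthetic experiments do and do not demonstrate.

## The peel-roughness metric

Ripening citrus peel grows smoother as epicuticular wax accumulates, so
local intensity variation is a ripeness signal. The metric works on the
fruit's axis-aligned bounding rectangle (of the mask's nonzero pixels when
a mask is supplied, of the whole image otherwise):

1. Both sides of the rectangle are divided into four equal parts; the nine
   interior intersection points are region centers. Non-integer division
   points are rounded half away from zero.
2. Each region's window is the quarter-size box
   `ceiling(H/4) x ceiling(W/4)` centered on its point, clipped to the
   rectangle. This tiles the rectangle with near-complete coverage without
   overlap tuning.
3. In each region, for each of the eight compass directions, the pixels on
   the half-ray from the center (center included) to the window edge are
   collected, and the mean absolute deviation from the ray mean is the
   direction's deviation `D_i`; the region value `P_i` is the mean of its
   eight deviations, and the overall roughness is the mean of the nine
   region values.

Half-rays rather than full lines through the center keep the eight
directional values distinct (full lines would collapse opposite directions
into four duplicates). Both rectangle sides must be at least 12 pixels, so
every window is at least 3×3 and every ray holds at least 2 pixels. Ray
pixels are read from the image even where they fall outside an irregular
mask: the metric operates on the rectangular crop, matching how bounding
rectangles of segmented fruit are scored.

The metric is linear in intensity scale, invariant under intensity
inversion, and exactly zero on constant images — properties the test suite
asserts.

## The R-LBP encoding

For a target pixel and each clockwise direction *d* (1 = top-left
diagonal, most significant bit), two arrays are compared:

* the *reference ray*: the intensities at offsets `1d, 2d, ..., (L+1)d`,
  where `L` is `ray_length` (default 2, so three pixels — the reference
  pixel and its collinear outward continuation);
* the *augmented ray*: the same array with the target pixel prepended.

The dispersion of an array is `sum((x - mean)^2) / (n * mean) * 100` — an
index-of-dispersion-like quantity, implemented exactly as specified rather
than the textbook standard-deviation-over-mean coefficient of variation.
The encoder only compares the two dispersions relatively, so the missing
square root changes which patterns cross the threshold but keeps the
construction well-defined; fidelity to the stated formula is what the
tests can check. The direction's bit is 1 when
`|CVa - CVb| / CVa > threshold` (default 0.15, strict), i.e. when adding
the target pixel changes the local variation by more than 15%.

Degenerate cases are explicit policy rather than accident:

* `CVa = 0` and `CVb = 0` (locally constant): bit 0, no texture;
* `CVa = 0`, `CVb > 0` (the target pixel introduces *all* the variation —
  an unboundedly large relative change): bit 1 by default, configurable
  via `zero_cv_policy`.

The geometry of the reference ray was an open choice: the construction
"the pixels in the reference pixel's direction" admits either a collinear
outward ray or a pair of flanking outer-ring pixels. The collinear reading
is implemented because it follows the direction literally, yields exactly
the three-term array the dispersion formula sums, and generalizes cleanly
through `ray_length`.

Borders: under `replicate_pad` (default) the image is edge-replicated by
`ray_length + 1` so every pixel receives a code; `zero_border` instead
leaves a zero band where the neighbourhood would exit the image. The
classic LBP baseline (`bit = neighbour >= center`, ties count as 1, same
bit order, replicate pad by 1) uses the same conventions so that
differences between arms are attributable to the encoding alone.

The compiled encoder accumulates sums sequentially in double precision;
the test suite's independent per-pixel oracle reproduces it bit for bit,
and code images are deterministic across runs.

## Composition of training images

`compose_scene()` replaces the fruit segment (mask = 1) by its R-LBP codes
and the background by plain grayscale. Two conventions matter:

* grayscale conversion is ITU-R BT.601 (`0.299 R + 0.587 G + 0.114 B`,
  rounded half away from zero) — the mainstream imaging convention, since
  no specific one is mandated by the method;
* encoding at fruit-border pixels reads neighbours from the full
  grayscaled image rather than a zeroed background, because zeroing would
  fabricate strong spurious edges at the mask boundary. Masks supplied by
  the caller stand in for manual (Photoshop-style) extraction, which is
  not implementable.

Outputs are PNG by default so tests can be bit-exact; JPEG export (quality
95) exists behind an explicit flag for interoperability with camera
pipelines. Detection label files are copied byte-identically because
composition never moves objects.

## The synthetic scene generator

`generate_fruit_scene()` renders a disc-shaped fruit (the mask is exactly
the disc inequality, no anti-aliased fringe) over a textured background.
The fruit surface is a *spatially correlated* Gaussian random field:
white noise smoothed with a Gaussian kernel (`texture_scale`, default 8
px) and normalized so its marginal standard deviation is `noise_sigma`.
One field is shared by all three color channels — chroma speckle would be
partially cancelled by grayscale conversion — and values are rounded and
clamped to 8 bits once, keeping scenes bit-reproducible for a given seed.

The correlation scale is a deliberate modelling choice. Peel relief in
close-range imagery spans several pixels (bumps and oil-gland dimples are
structures, not per-pixel flicker). It is also load-bearing: ordinal code
statistics (LBP-family) are almost invariant to the amplitude of spatially
*independent* noise — apart from 8-bit quantization ties, rescaling an
i.i.d. field does not change which neighbour exceeds which — so a purely
i.i.d. surface cannot show amplitude-driven code-texture differences at
all. With a correlated field, local gradients scale as
`noise_sigma / texture_scale`; at ripe-stage amplitudes they approach the
quantization scale, ties and near-constant rays appear, and code images
become visibly calmer — exactly the smooth-peel behaviour the encoding is
designed to detect.

A four-stage series (A least ripe … D ripest) fixes geometry, seed and the
background realization, and varies:

* surface amplitude `sigmas = c(30, 20, 12, 5)` — strictly decreasing, the
  smoothing trend of ripening; values chosen to give a clear, realistic
  spread of roughness across stages (no quantitative stage-vs-roughness
  calibration is available to match);
* base peel color, green `(70, 150, 60)` through orange `(245, 160, 40)`.

The background (`bg_rgb = (55, 95, 50)`, field std 18 smoothed by
`bg_blur_sigma = 4`) supplies leaf-like low-frequency texture distinct
from the fruit's finer field. Substream seeds (background, and one per
stage) are derived disjointly from the base seed so that groups produced
by `generate_group_set()` (consecutive base seeds) never share a field.

**What passing tests do and do not show.** The generator emulates the
*mechanism* — amplitude of structured surface texture falling with
ripeness on a colored disc — not orchard photographs: no illumination or
backlight, no occlusion, no perspective, no multi-fruit layouts, no sensor
noise. Experiments on it demonstrate that the implementation orders and
amplifies texture differences as designed; they do not certify performance
on real imagery.

## The experiment harness

For each four-stage group, each stage's fruit crop (mask bounding
rectangle) is grayscaled, transformed per arm (`grayscale` = identity,
`lbp`, `rlbp`), and scored with `peel_roughness()`; the group value is the
mean of the three absolute adjacent-stage differences. Per-arm
distributions over groups are summarized by median, quartiles and IQR,
with quartiles by linear interpolation between the closest order
statistics (`quantile()` type 7; the convention is documented because no
particular one is mandated, and with `{1,2,3,4,5}` it gives q1 = 2,
q3 = 4). Differences are averaged within groups before pooling, matching
the per-group design of the study.

Default problem sizes — 50 groups of four 256×256 scenes (disc radius 60,
fruit crop 121×121) — keep a full three-arm run around ten seconds on one
CPU, while leaving stage orderings stable across seeds; the acceptance
tests run the full set over a five-seed panel.

## Known limitations

* The roughness metric has a single scale: no multi-scale aggregation, no
  sub-pixel ray sampling, no rotation-invariant pooling beyond the eight
  fixed directions.
* The encoder implements the printed dispersion formula; a conventional
  CV (with square root) would fire on different patterns. The choice is
  documented, not empirically arbitrated.
* The 16-bit input path only rescales to 8 bits (integer division); there
  is no 16-bit processing, EXIF handling or color management.
* Synthetic-data conclusions transfer to real orchards only qualitatively
  (see above).
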