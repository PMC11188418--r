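# rlbp

Texture tools for fruit ripeness imaging: a peel-roughness metric, the
R-LBP (Roughness Local Binary Pattern) encoding, and the compositing
pipeline that turns segmented fruit photographs into texture-enhanced
detector training images.

## The problem

As citrus fruit ripens, epicuticular wax accumulates and the peel becomes
smoother, so surface texture carries ripeness information that color alone
does not — unripe green fruit is nearly the color of the leaves behind it.
This package quantifies that texture and amplifies it:

**Peel roughness.** For a fruit's bounding rectangle, both sides are
divided into four equal parts; the nine interior intersection points define
sampling regions (each a quarter-size window). In each region, along each
of the eight compass directions *i*, the mean absolute deviation

&nbsp;&nbsp;&nbsp;&nbsp;D<sub>i</sub> = Σ |X<sub>i</sub> − X̄| / N

is computed over the N pixels of the ray from the region center, and the
region value is P<sub>i</sub> = Σ D<sub>i</sub> / 8. The overall roughness
is the mean of the nine region values. Smooth (ripe) peel scores low.

**R-LBP encoding.** For every pixel, and for each of the eight clockwise
directions, two dispersions are compared: CV<sub>a</sub>, computed on the
outward ray of pixels in that direction (the reference pixel and its
collinear continuation), and CV<sub>b</sub>, on the same ray with the
target pixel prepended. Dispersion is Σ(X<sub>i</sub> − X̄)² / (n X̄) × 100.
The direction's bit is 1 when |CV<sub>a</sub> − CV<sub>b</sub>| /
CV<sub>a</sub> > 15%, i.e. when the target pixel meaningfully changes the
local variation; the eight bits (direction 1 most significant) form the
pixel's new 8-bit value. A classic 3×3 LBP is included as the baseline.

**Composition.** Training images are built by replacing the fruit segment
(given as a binary mask) with its R-LBP encoding while the background is
reduced to grayscale, and detection label files are passed through
unchanged.

A seeded synthetic scene generator (disc-shaped fruit with a spatially
correlated surface field whose amplitude falls with ripeness, on a leafy
background) makes every stage of the pipeline testable without orchard
data, and an experiment harness summarizes per-group adjacent-stage
roughness differences under the three preprocessing arms (grayscale, LBP,
R-LBP) by median, quartiles and IQR.

## Worked example

```r
library(rlbp)

# a four-stage ripeness series (A least ripe ... D ripest), seeded
series <- generate_stage_series(scene_spec(seed = 7))
sapply(series$scenes, function(sc)
  peel_roughness(to_grayscale(sc$image), sc$mask)$overall)
#> [1] 8.06 5.42 4.57 3.02        # roughness falls as the fruit ripens

# mean adjacent-stage roughness difference under the three arms
for (m in preprocess_methods())
  cat(m, round(group_difference(series, m), 2), "\n")
#> grayscale 1.68
#> lbp 8.26
#> rlbp 9.2                       # R-LBP amplifies the stage contrast

# the full experiment over seeded groups
groups <- generate_group_set(10, scene_spec(seed = 7))
run_experiment1(groups, "rlbp")
#> Roughness-difference distribution [rlbp]: n = 10
#>   median 10.08, q1 8.98, q3 10.60, IQR 1.63
```

The roughness values fall monotonically from stage A to D because the
generator lowers the surface-texture amplitude as the peel ripens; the
R-LBP arm's stage differences are several times the grayscale arm's, which
is the property that makes the encoding useful for ripeness
discrimination.

## Command line

```sh
rlbp transform in.png -o out.png --threshold 0.15   # R-LBP code image
rlbp roughness in.png --mask mask.png --json r.json # peel roughness
rlbp compose in.png --mask mask.png -o train.png    # training composite
rlbp simulate --out scenes/ --seed 7 --groups 50    # synthetic dataset
rlbp experiment1 --scenes scenes/ --method rlbp --json stats.json
```

The script is installed at `exec/rlbp` inside the package directory; it is
a thin wrapper over `rlbp::run_cli()`.

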