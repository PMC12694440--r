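---
title: "Canopy profiling from RGB-D imagery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy profiling from RGB-D imagery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teaprof)
```

## The problem

A bulk-tea harvester cuts the entire top of the canopy with an arc-shaped
reciprocating cutter. The cut should run a fixed distance `L` (the
bud-layer length, here 10 cm) below the canopy's upper surface and stay
parallel to it while the machine travels over sloping, unevenly grown
rows. `teaprof` implements the perception side of that control loop: given
a pixel-aligned RGB + depth frame looking straight down at the canopy, it
estimates where the *young shoot* surface is and what height and rotation
correction the cutter needs.

The crucial modelling point is that a raw depth average over the frame is
biased: gaps in the canopy expose older, deeper leaves, and their depths
drag the mean away from the shoot surface. The pipeline therefore first
identifies shoot pixels in colour and only averages depth over those.

## Shoot segmentation

Young shoots are vivid green (G well above R and B); the older leaves
beneath them are shaded and darker in all channels. The excess-green index

$$\bar G = 2G - R/2 - B$$

amplifies that difference into a near-bimodal gray histogram. We read the
expression with the precedence `2G - (R/2) - B`, evaluate it in floating
point, clamp to [0, 255] and quantize to 8 bits; exact halving of R (no
integer truncation) keeps the index monotone in the channel values. For
any green-dominant pixel (`G >= R`, `G >= B`) the index is at least `G/2`,
which is why shoots land in the bright mode.

Outdoor illumination changes the gray-level geometry of the problem, so
the frame's **AG value** — the mean Rec.601 luminance
(0.299, 0.587, 0.114) over the whole frame — dispatches between two
branches:

* **Low light, AG in [90, 140):** overcast/cloudy frames are flat in
  contrast. CLAHE (clip limit 2.0, 8 × 8 tile grid) is applied to the
  luminance component, with the colour channels rescaled by the luminance
  gain so chromaticity is preserved, restoring the bimodality before
  thresholding.
* **High light, AG in [140, 220]:** direct sun produces saturated specular
  patches that corrupt the index. Pixels whose *minimum* channel reaches
  the specular threshold (default 230) are marked, zeroed, and excluded
  from thresholding; after segmentation they are forced to background.

AG boundaries are half-open exactly as stated: 140 belongs to the high
band. AG values outside [90, 220] are rejected with a classed error rather
than silently binned — the two branches are only calibrated inside their
bands — but the caller may override the class explicitly
(`force_class`), which the CLI exposes as `--force-class`.

Thresholding uses **Otsu's criterion**: the split of the (possibly
zero-excluded) 8-bit histogram maximizing the between-class variance, with
ties broken toward the lower threshold so the result is deterministic. The
implementation is an exhaustive scan over all 256 candidate levels; an
independent brute-force maximizer in the test suite must agree on every
random image, with and without zero exclusion. Degenerate inputs (fewer
than two distinct eligible levels) raise a classed error instead of
returning an arbitrary level. Foreground is the *bright* class
(`index > threshold`), since shoots are the bright mode of the index.

The binary mask is cleaned by **morphological erosion** with a 3 × 3
square element, one pass by default. Erosion removes isolated
false-positive pixels at the cost of one boundary layer of true shoot
pixels; both effects are visible in the pixel precision/recall the tests
measure. Kernel and iteration count are configuration, not constants.

Two choices here are deliberately ours, because the method leaves them
open: the specular rule (minimum channel ≥ threshold, the simplest rule
that captures "all channels saturated") and the AG region (the whole
frame, since the camera is aimed at the canopy; a sub-region can be
configured).

## Depth profiling

Depth rasters arrive in integer millimetres with 0 as the invalid
sentinel (the common RGB-D convention). Preprocessing is two steps:

1. **Plausible-range gate** [`min_depth_mm`, `max_depth_mm`], default
   [200, 2000] mm — wide enough for a cutter-mounted camera at roughly
   45–72 cm above the canopy, tight enough to reject holes and the ground
   seen through gaps. Out-of-range pixels become invalid.
2. **Invalid-aware median filter**, default 5 × 5: each window's median is
   taken over its valid pixels only, and invalid pixels stay invalid. A
   conventional median filter would smear the 0 sentinel into the data;
   no installed package offers the masked variant, so it is implemented
   here and checked against a brute-force per-window oracle.

`l_near` and `l_far` are then the mean depths (reported in cm) of pixels
that are simultaneously inside the configured region, shoot foreground,
and valid. Region rectangles are fractions of the image extent, mapped to
pixels as the half-open range `floor(lo·extent) .. floor(hi·extent)` so
pixel counts are reproducible at any resolution. The defaults — central
columns 4/14–10/14, left columns 1/14–2/14, rows 3/8–5/8 for both — balance
sensitivity against robustness: a narrower central region over-reacts to
single tall shoots, a wider left region reaches into the canopy's curved
shoulder.

If a region contains fewer than `min_valid_pixels` (default 25)
contributing shoot pixels, the region average falls back to the mean over
*all* valid pixels there and the report flags it: a harvester must emit a
pose every frame, and a flagged biased estimate is more useful than a
halt. The strict variant (`region_mean_depth()`) raises a classed
insufficient-evidence error instead.

## Cutting pose and motion logic

With `a_near`, `a_far` the fixed vertical distances from the camera to the
cutter's centre and left end, the corrections are

$$d = a_\mathrm{near} - l_\mathrm{near} - L, \qquad
\alpha = \left(L - (a_\mathrm{far} - l_\mathrm{far})\right)\frac{180}{r\,\pi},$$

`d` in cm (positive = raise the cutter), `α` in degrees. Sign conventions
are fixed by the formulas: a canopy deeper than ideal on the left
(`l_far` large) gives positive `α`, rotating the left end *down* toward
the canopy. The default `r = 114` cm (rotation point to cutter's left end)
is a package default standing in for a rig-specific measurement; every
geometry constant is a `rig_config()` field.

The rotation is actuated through a triangle linkage (bracket `b`, radius
`r`, actuator chord `c`). Rather than iterating on the law-of-cosines
relation, the displacement is inverted in closed form:
`θ₀ = arccos((b² + r² − c²)/(2br))`, `θ₁ = θ₀ + απ/180`,
`Δx = √(b² + r² − 2br·cos θ₁) − c`. Requests pushing `θ₁` outside `(0, π)`
or the arccos argument outside [−1, 1] raise a mechanism-limit error. The
principal arccos branch makes the added-multiples-of-2π form of the
relation unnecessary. A numeric root-finder exists only as a test oracle;
the forward map must recover `α` to 1e-9 across a grid of linkage
geometries.

The discrete **motion decision** is a lookup in a band table over
(`l_near`, `l_far`). The default table splits each axis into three
closed-open bands — near: low [35, 43), ideal [43, 47), high [47, 55);
far: low [47, 51), ideal [51, 55), high [55, 59) — whose 3 × 3 grid plus
per-axis out-of-range gives the machine's ten motion types. Vertical
action follows the near band directly. Rotation follows the far deviation
*after* the height correction (the cutter translates as a whole before it
rotates), which is what couples the axes: a cutter that is low with the
far side ideal must rise *and* rotate down. When one axis is out of
range, the other is still decided from its own band. Tables are validated
at load time — non-overlapping, gap-free bands and a complete rule grid —
never at query time, and are fully replaceable via JSON configuration.

## The synthetic canopy generator

No public dataset of nadir bulk-tea RGB-D frames exists, so the package
generates its own study material with exact ground truth. A frame is
deterministic in its seed (one local RNG stream; global RNG state is
untouched):

* **Shoots:** a union of random ellipses (semi-axes ~18–40 px at 240 px
  image height) with per-blob green jitter, grown until the requested
  cover fraction (default 0.45) is reached; because bulk shoots spread
  over the whole canopy top, both measurement regions are additionally
  topped up to a minimum cover so region averages are always defined.
* **Depth:** `depth(u) = peak + sag·u² + tilt·u` cm, `u ∈ (−1, 1)` the
  normalized horizontal offset — a symmetric convex arc (default peak
  45 cm, sag 6 cm) with optional linear tilt. Old-leaf pixels sit
  `old_leaf_depth_offset` (default 6 cm) deeper, which is what makes mask
  conditioning matter. Gaussian noise (default sd 3 mm) and a hole
  fraction (default 2%, sentinel 0) are added; rasters are quantized to
  integer mm, so noise-free region means match truth to within half a
  millimetre of rounding.
* **Colour:** shoots are rendered green-dominant by construction
  (G strictly above R and B before illumination); old leaves are darkened
  (factor 0.55) with patchwise brightness texture and per-pixel sensor
  noise (sd 6). The brightness patches use channel weights (2, 1, 1),
  which cancel exactly in the excess-green index: old-leaf *greenness*
  varies only at pixel scale, so a shootless frame thresholds into
  isolated salt that erosion removes. This is the property that makes the
  negative control (no shoots → near-empty mask) hold.
* **Illumination:** a global gain found by deterministic bisection so the
  frame's AG lands at 120 (low preset) or 168 (high preset) — mid-band
  values matching overcast and sunny field readings; the generator
  self-checks the band after quantization. Specular patches are saturated
  discs (all channels ≥ 243) excluded from the gain search.
* **Truth:** the shoot mask, the exact area-weighted mean of the
  *noise-free* surface over shoot pixels in each region, and the pose
  (`d`, `α`) implied by the rig.

What the generator does **not** emulate: leaf-scale texture and shape,
occlusion ordering, lens distortion, oblique camera mounts, motion blur,
or correlated depth artefacts of a real stereo sensor. Passing the
recovery tests therefore demonstrates the pipeline's internal
consistency — that segmentation, masked averaging and pose computation
recover known truth under controlled noise — not field performance.

## Numerical conventions

* Reported percentages and table values round half *away from zero*
  (`round_half_up()`), matching printed-report conventions; comparisons in
  tests use each printed value's own precision.
* Trial aggregation uses the *population* SD (divide by n) — the
  convention consistent with published harvest-trial tables.
* Pixel-level confusion counts define detection P/R/F1; with masks as the
  unit of comparison, instance-level counting is not meaningful here.
* Degenerate inputs fail loudly with classed conditions
  (`teaprof_parameter_error`, `teaprof_degenerate_histogram`,
  `teaprof_insufficient_evidence`, `teaprof_mechanism_limit`,
  `teaprof_lighting_error`, `teaprof_config_error`); the CLI maps the
  operational ones to distinct exit codes.
* Otsu ties break toward the lower threshold; erosion uses a box element;
  region bounds are half-open — all so that identical inputs give
  identical outputs everywhere.

## Problem sizes

Tests and examples run on 240 × 320 frames (the default), with brute-force
oracles on rasters up to 128 × 128 and 200 random 64 × 64 images for the
Otsu equivalence suite; the linkage round-trip sweeps a grid of
(b, r, c, α) combinations. These sizes keep the full suite under a couple
of minutes while leaving every property scale-free: the fraction-based
regions, the gain calibration and the band logic do not depend on the
frame size.

## Known limitations

* The high-light branch applies no CLAHE; frames that are simultaneously
  dim and specular are outside the calibrated regimes.
* Specular-occluded shoot pixels are unknowable to the segmenter by
  design; recall is bounded by the non-specular shoot fraction.
* The fallback region average (too few shoot pixels) is biased toward the
  old-leaf surface and is flagged, not corrected.
* `α` is a small-angle approximation (`arc ≈ chord`); for the default rig
  it stays well under 5°, where the error is negligible.
* One frame drives one correction; no temporal smoothing or prediction
  across frames is attempted.
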