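---
title: "Methods: minority-class copy-paste augmentation for cell instance segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minority-class copy-paste augmentation for cell instance segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepwise)
```

`deepwise` prepares stained bone-marrow aspirate images for plasma-cell
instance segmentation: it removes unstained cells, grows the minority cell
class by copy-paste augmentation with edge-restricted gradient-domain
blending, and scores instance predictions. This vignette is the package's
account of the underlying models, the defaults, and the decisions taken
where the design was genuinely open.

## Coordinate and raster conventions

Images are `H x W x 3` integer arrays with 8-bit channels; masks are
logical matrices. Continuous coordinates are 0-based with `x` along
columns, `y` along rows and the origin at the top-left; pixel `(r, c)`
spans `[c, c+1) x [r, r+1)` and has center `(c + 0.5, r + 0.5)`. A pixel
belongs to a polygon iff its center is inside under the even-odd rule;
centers lying exactly on an edge resolve by the same crossing-parity test,
so rasterization is deterministic for vertices on pixel-center lines.
Wherever intensities are quantized, rounding is half-to-even, which is
reproducible across platforms.

Tracing a mask back to polygons walks the outer boundary of each
8-connected component along pixel-grid corners. At a *pinch* corner (two
pixels meeting only diagonally) the trace crosses onto the diagonal
neighbour, so an 8-connected component always yields a single ring.
Interior holes are filled on tracing: cell annotations are simple closed
regions, and supporting multi-ring polygons was deliberately left out.
Consequently `rasterize(trace(M)) == M` exactly for every hole-free
component ("hole-free" meaning the complement is 4-connected to the image
border), and equals the filled component otherwise.

## Stained-cell preprocessing

On stain-normalized smears, the cells of interest are bluish, unstained
material (mostly red blood cells) pinkish, and the background pinkish
white. The preprocessing stage has four steps.

**Percentile contrast stretching.** Each channel (or all jointly with
`per_channel = FALSE`) is mapped by
`v' = clip((v - p_lo) * 255 / (p_hi - p_lo), 0, 255)` with `p_lo`, `p_hi`
the channel's `low_percentile`/`high_percentile` quantiles (type-7
quantiles, the R default). Defaults are 2 and 98: percentile rather than
min/max clipping is robust to specular outliers. A channel whose two
percentiles coincide is left unchanged with a message. The map is monotone
per channel, and idempotent once the configured percentiles already sit at
0 and 255.

**Greenish-pixel detection.** Stretching pushes the pinkish unstained
material into green dominance. "Greenish" is operationalized as
`G - max(R, B) >= green_margin`, default 10 intensity units — the simplest
testable reading, and exposed in `unstained_rule()`. The raw flag map is
cleaned by a morphological opening (radius 2) and a minimum
connected-component size (50 px). Those cleanup defaults are stated at the
2560 x 1920 scale of typical scanner output; `scale_unstained_rule()`
scales the area threshold linearly with image area and the radius with its
square root. Morphology uses the unit-radius disk (the 4-neighbour cross)
iterated `r` times; an `r`-fold iterated unit disk (a diamond of radius
`r`) was chosen over a Euclidean disk because it is exact, fast and
testable against brute-force neighbourhood checks.

**Background model.** Median and spread per channel over all pixels
outside an exclusion mask (annotated cells plus detected unstained pixels).
The spread is `stats::mad()` — the median absolute deviation scaled by
1.4826 — so that for Gaussian backgrounds it estimates the actual standard
deviation and the replacement noise visually matches the surrounding
texture.

**Replacement.** Flagged pixels become the background median plus seeded
zero-mean Gaussian noise with the model's spread, clipped and rounded;
pixels outside the flag mask are untouched bit-exactly, and with zero
spread the fill is exactly the median. A flat statistical fill (rather
than inpainting) is enough for the stated purpose — leaving no additional
regions for a segmenter to find — and is reproducible. The hue channel
(`hue_channel()`, standard RGB-to-HSV hue rescaled to [0, 255], achromatic
pixels 0) is provided for inspecting stained/unstained separability; the
removal pipeline itself operates on stretched RGB, which separates the
classes better.

## Deep-wise augmentation

Whole-image augmentation grows majority (non-cell) and minority (cell)
pixels together. The copy-paste strategy grows only the minority class:

1. **Extraction.** Every annotated cell is rasterized and cropped to its
   bounding box (`cell_patch`); mask pixels carry the source colours
   verbatim, and crop pixels outside the mask are kept only as blending
   guidance.
2. **Transforms.** The default set — `flip_h`, `flip_v`, `rot90`, `rot180`,
   `rot270` (`rot90` is 90 degrees clockwise on screen) — consists of exact
   pixel permutations: mask areas and colour values are conserved
   verbatim, which matters because the cell interior is the pathology.
   `rot_free` (bilinear colour, nearest-neighbour mask, canvas expanded to
   the rotated extent) exists but is off by default precisely because it
   resamples.
3. **Placement.** Backgrounds are drawn uniformly from the existing
   training images, so no new majority-class pixels are created. Positions
   are rejection-sampled under three constraints: pasted cells may cover at
   most 10% of any original cell's area (cumulatively), any two pasted
   cells have IoU at most 0.1 (allowing the touching/overlapping rims seen
   in real clusters), and a candidate's dilated mask may never reach an
   already pasted cell's eroded interior — without this last rule a later
   paste's blend band could rewrite an earlier interior and break the
   preservation guarantee below.
4. **Edge-band blending.** With band half-width `k` (default 3 px, small
   enough to leave the morphology of the cell untouched), the mask is split
   into the `k`-eroded *interior*, the *band* between erosion and
   `k`-dilation, and the exterior. Per channel, band values solve the
   discrete Poisson equation: for each band pixel `p`,
   `sum_{q in N4(p)} (f(p) - f(q)) = sum_{q in N4(p)} (g(p) - g(q))`,
   where the guidance `g` is the composite inside the mask and the
   background outside, and Dirichlet values come from the fixed interior
   (composite) and exterior (background). Band pixels on the image border
   are fixed to the background. The system is symmetric positive definite
   and small (a band around a cell is hundreds to a few thousand unknowns),
   so it is solved by sparse direct factorization (`Matrix`); the relative
   residual is still checked against `solver_tol` (default 1e-8) and an
   error raised if it is not met. `max_iter` is reserved for iterative
   solvers and unused by the direct path. Blending is per-channel RGB;
   the colour space is configurable by preprocessing the inputs, and RGB
   is the default because the preserved interiors are RGB data anyway.

The three resulting guarantees, which the test suite asserts bit-exactly,
are: interiors equal the transformed patch; pixels outside all dilated
masks equal the background; and the non-cell pixel count never increases
from background to augmented image. A full feature-loss blending
refinement (as in learned image blending) would break none of these but
adds nondeterminism and heavy dependencies; the band-restricted Poisson
solve meets every stated property and is the default and only mode.

All randomness — background choice, patch and transform sampling,
placement, fill noise — flows from the single integer seed in
`placement_policy()` through one documented stream order, so an augmented
dataset is a pure function of (inputs, seed).

## Evaluation

Ground truth and predictions are `instance_set`s of binary masks (with
optional confidences). Matching is greedy: predictions in descending score
order (ties or missing scores: descending best-IoU, then index) claim
their highest-IoU unclaimed ground-truth instance if that IoU reaches the
threshold (default 0.5). Greedy matching is the field's standard
convention; the test suite compares it against an exhaustive assignment
oracle on small scenes and counts the (rare) cases where a different
assignment could match more pairs.

From `TP` matched pairs, `FP` unmatched predictions and `FN` unmatched
ground truths: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and mean IoU
over matched pairs only — unmatched instances already show up in precision
and recall, and keeping the three numbers independent makes them
interpretable. Conventions at the boundaries, documented because they are
genuinely ambiguous: with zero predictions, precision is 1 if there are
also zero ground truths and 0 otherwise (symmetrically for recall), and
mean IoU is 0 whenever nothing matched. Dataset aggregation reports both
the macro average (equal weight per image — the default) and the micro
pooling of counts and matched IoUs; whether published mean metrics are
per-image or pooled is rarely stated, so both are always computed.

## The synthetic generator

`synth_config()`/`generate_image()` draw seeded microscopy-like scenes:
Gaussian-noise background, stained cells as ellipse pairs (nucleus inside
cytoplasm, the cytoplasm outline is the ground-truth polygon), unstained
cells as larger ellipses possibly underneath stained cells (the truth mask
contains only their visible pixels), and clusters: with probability
`cluster_prob` a cell is seeded at 85–98% of the minor-axis sum from an
existing cell, guaranteeing touching or slightly overlapping cytoplasm.
Ellipses rather than learned textures: the properties under test — colour
separability, touching topology, occlusion — do not require realism, and
analytic geometry gives area oracles for free. The default canvas is
512 x 512 for desk-scale work; full 2560 x 1920 is accepted and all
size-dependent defaults rescale.

The colour model is a deliberate calibration, not an afterthought. A
per-channel percentile stretch saturates the top 2% of every channel, so
*which class occupies a channel's upper tail* decides how the stretched
image behaves. The defaults make unstained cells numerous and large enough
(counts 5–8, 1.3x axis scale, together a few percent of the canvas) to
anchor the green channel's 98th percentile, while the background anchors
red and blue. That reproduces, by construction, the property of real
stain-normalized smears that stretching turns unstained material greenish
with a wide margin (tens of stretched intensity units) over background and
cytoplasm. What the generator does *not* emulate: real chromatin texture,
soft cell boundaries, illumination gradients, stain variability between
slides. Tests passing on synthetic scenes therefore validate the
*mechanics* (exactness, determinism, set algebra, solver correctness) and
the pipeline's behaviour under the modelled colour geometry — not clinical
performance on real smears, which depends on downstream detector training
that is explicitly out of scope.

## Degenerate inputs and tie-breaks

* Zero-area polygons rasterize to an empty mask with a warning (not an
  error); annotations that rasterize empty are skipped at extraction.
* `edge_band()` on a mask whose interior erodes away makes the whole
  dilated mask the band (with a message); a single isolated pixel is then
  pure band.
* A patch that cannot be placed within `max_attempts` is skipped with a
  warning; an augmentation producing no cells at all is an error.
* `mask_iou` of two empty masks is 0 by convention.
* Quantile ties in contrast stretching (constant channels) return the
  channel unchanged.
* VIA files: only the 2.x project flavour is accepted, loudly; non-polygon
  regions are skipped with a warning; polygons with fewer than 3 points
  are an error naming the image and region.

## Problem sizes

The shipped test-suite and acceptance script run at desk scale, chosen as
the package's own working sizes: 128–160 px canvases for augmentation
scenes (cells of 4–8 px radius), the generator's 512 px default for the
preprocessing study (20 and 10 seeded images respectively), 16 px scenes
with bands of at most 500 unknowns for the dense-solver comparison, and
7 x 7 to 14 x 14 masks for the metric and round-trip oracles. All fixtures
are generated in code from fixed seeds; nothing is stored.

## Known limitations

* One polygon per cell: nucleus/cytoplasm sub-masks are not modelled.
* Polygons with holes are filled on tracing (documented above).
* 8-bit RGB only; 16-bit imagery is out of scope.
* The BMP reader/writer covers the uncompressed 24-bit flavour only.
* `rot_free` resamples colours; use the exact transforms when interior
  fidelity matters (they are the default).
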