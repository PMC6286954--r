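---
title: "Dual-season crown delineation: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-season crown delineation: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownseg)
```

## The measurement model

`crownseg` measures open-centre fruit trees from two co-registered digital
surface models (DSMs) of the same orchard block: a leaf-off scene in which
each tree appears as a set of thin elevated ridges (the permanent scaffold
limbs) and a foliated scene in which crowns are smooth dome-like surfaces
that may touch their neighbours. The key assumption is that the scaffold
seen in winter sits inside the crown grown over it in summer: the winter
scene therefore supplies one reliable *seed region per tree*, which is what
a watershed segmentation of irregular, multi-maximum crowns otherwise
lacks. A naive watershed seeded at local maxima splits a single open-centre
crown into one segment per limb; seeding it with exactly one marker per
tree removes over-segmentation by construction, and the only remaining
failure modes are missing markers (a tree invisible in winter) and crowns
whose true boundary differs from the height saddle between neighbours.

The pipeline is deliberately deterministic from end to end. Every stage is
a pure function of the rasters and the configuration; the watershed's
flooding order (highest candidate first, FIFO among equal heights,
neighbours pushed in a fixed N, E, S, W, NE, SE, SW, NW order, seeds taken
in raster-scan order) resolves every tie explicitly, so two runs on the
same inputs produce bit-identical label rasters.

## Stages and their parameters

### Adaptive threshold

A cell is canopy foreground iff its height strictly exceeds
`sensitivity × (local mean of valid heights in a window centred on it)`.

* `sensitivity` (default **0.9**, range (0, 1]): a multiplicative margin on
  the local mean. Lowering it raises the effective bar and drops low canopy
  first — the characteristic failure is the loss of low lateral branches.
* `window` (default: **half the smaller grid dimension**, rounded up to
  odd): the averaging scale. Two constraints bound it. It must exceed the
  crown diameter, otherwise the local mean tracks the crown surface itself
  and crowns are hollowed out; and every window position must contain some
  canopy as well as ground, otherwise a window of bare ground has a local
  mean at ground level and the multiplicative rule admits roughly half the
  ground noise as foreground. In a regular planting both are satisfied once
  the window spans at least one planting interval, with the field margin
  kept below half the window so border neighbourhoods still reach a tree.
  The package default of half the smaller scene dimension satisfies this
  for typical single-block scenes; for very large multi-block rasters set
  `window` to one-to-two planting intervals explicitly.

The local mean uses summed-area tables over valid (non-nodata) cells, so
masked regions and photogrammetric holes dilute nothing.

### Despeckle and closing (winter scene)

The thresholded winter mask passes through an area opening
(`despeckle_min_area`, default **64 px**) before the morphological closing.
This ordering matters: closing with a diamond of radius 50–80 px turns any
isolated noise pixel into a tree-sized blob, so speckle must be removed
*before* closing, not after. Scaffold components are three to four orders
of magnitude larger than noise speckle, so the cut-off is uncritical
anywhere in between.

Closing uses the diamond (L1-ball) structuring element
`{(di, dj): |di| + |dj| ≤ r}` with `closing_radius` (default **50 px**;
leaf-off orchard scenes at sub-centimetre resolution typically need 50–80
depending on branch spacing). It must exceed half the largest within-tree
gap between limbs and stay below half the between-tree scaffold gap.
Dilation and erosion are computed exactly via two-pass city-block distance
transforms. At the raster border, erosion treats outside cells as
foreground (the pad-with-ones convention): this keeps closing *extensive*
(output ⊇ input) on a bounded grid, which the pipeline relies on — a
scaffold touching the field edge must not be eaten by its own closing.

Components smaller than `min_area` (default **25 px**) are then discarded
and the survivors labelled in raster-scan order (`connectivity` default 8,
matching the visual contiguity of thin branches).

### Convex hulls, markers, watershed, merging

Each scaffold's convex hull is filled with the cell-centre rule and its
area centroid recorded; 1–2-pixel and collinear components are flagged
degenerate rather than rejected. Markers are hull ∩ summer-foreground;
where two hulls overlap, the contested pixel goes to the nearer centroid
(ties to the lower tree id), and trees with empty markers are reported as
unseeded rather than silently dropped. The watershed floods the negated
summer heights inside the foreground mask; no watershed-line pixels are
kept (crowns are space-filling), because the downstream area metric wants a
partition, not ridgelines. Foreground components untouched by flooding —
typically detached tufts at crown rims — are merged wholesale to the tree
with the nearest hull centroid, with no size cut-off by default
(`max_merge_area = Inf`); after merging, labelled pixels equal foreground
pixels exactly, an invariant the test suite asserts on every scene.

### Metrics

`CPA = pixel count × resolution²` exactly. Widths come from the bounding
box in a frame rotated by `-row_angle` so `W1` lies along the planting row;
extents are `max − min + 1` pixels, so a one-pixel crown has the physical
size of one pixel rather than zero — at sub-centimetre resolution the
+1 convention is far below measurement error either way. The field-survey
relation `CPA_f = coefficient × W1f × W2f` defaults to the locally
calibrated ellipse-like factor **0.65** and is exposed as a parameter
because it is an orchard-specific empirical constant, not a geometric law.

Evaluation statistics are squared Pearson correlation (not
regression-through-origin R²), RMSE, and RMSE relative to the reference
mean in percent. Growth rates follow the discrete definitions
`GR = ΔCPA/Δt` and `RGR = ΔCPA/(CPA_start · Δt)` with `Δt` in whole
calendar days; `RGR` is dimensionally 1/day and is reported as such (field
reports sometimes print RGR in m⁻² day⁻¹; the definition above is what the
package computes).

## The synthetic orchard

The simulator emulates the scenes this method is designed for, at the
study's scale: a 3 × 4 grid of trees at 6 m spacing on a 1 cm/px grid
(≈1800 × 2400 px), open-centre scaffolds with two predominant limbs
perpendicular to the row plus minor limbs, ridge heights 1.5–3 m, and
in-season ellipsoidal-cap crowns `h·sqrt(1 − (d/r)²)` composited by
pointwise maximum, with per-tree radii, heights and limb geometry drawn
from a seeded RNG. An `overlap_factor` inflates all radii to push
neighbours into contact; contested truth pixels belong to the taller
surface. An optional two-lobe `open_centre` crown profile produces the
multi-maximum shapes that over-segment an unseeded watershed.

Measurement error is modelled in two steps: i.i.d. Gaussian height noise
(`noise_sd`, default **0.02 m**) followed by a Gaussian surface smoothing
(`smooth_sd`, default **0.02 m** on the ground). The smoothing is on by
default and represents the low-pass character that photogrammetric noise
filtering imprints on every real SfM surface model — raw per-pixel white
noise at 2 cm on a 1 cm grid describes no DSM that this pipeline would
ever receive, and under it no multiplicative local-mean rule can separate
flat ground from thin scaffolds at any sensitivity ≤ 1 (the scaffold's
contribution to a window mean is ~1–3 cm while the tail of the raw noise
reaches 10 cm). The smoothing also reproduces two documented behaviours of
real data: crowns look slightly "bloated" relative to their true footprint,
and width errors grow at coarse resolution where the smoothing radius is a
larger fraction of the crown.

Truth labels and truth crown records are computed from the noiseless,
unsmoothed footprints, so the simulator's truth is independent of the
measurement-error model.

What passing the simulated tests does **not** show: robustness to
co-registration error between the two seasons (the generator shares exact
tree positions), to sloped or terraced ground beyond a linear plane, to
nodata holes inside crowns, or to the species- and training-specific
geometry of real orchards. Those remain field-validation questions.

## Numerical and degenerate-input choices

* Cell-inclusion for polygons and hulls is centre-in-region with boundary
  counted inside (even-odd rule, tolerance 1e-9); masking is idempotent and
  never edits interior values.
* Height ties in the watershed are resolved FIFO; label ties (equidistant
  centroids) resolve to the lower tree id — both chosen to make every
  output reproducible rather than platform-dependent.
* All-nodata rasters, empty foregrounds, empty marker sets, non-coregistered
  raster pairs, non-increasing dates and non-positive starting CPA are
  errors naming their stage; empty *label sets* in `crown_metrics()` are an
  empty table, not an error.
* Rasters are written as Esri ASCII grids (text, exact for integer labels,
  ~1e-8 relative for heights); TIFF is read-only with a JSON sidecar for
  the pixel size, because no installed raster backend writes georeferenced
  float TIFFs.

## Problem sizes used by the test suite

Unit tests run on 120 × 180 to 220-px coarse scenes (5 cm pixels, 6 trees)
chosen so each stage's geometry (window, closing radius, margins) scales
the same way as the survey-scale scenes; the whole-method recovery test
uses twenty seeded 1800 × 2400 px scenes at 1 cm/px with 12 trees,
`noise_sd` 0.02 m and no crown overlap, asserting exact tree count, CPA
within 5% and widths within 3 px of truth for at least 95% of trees.
Watershed correctness is established against an independently written
ordered-flooding oracle on a hundred random ≤20 × 20 scenes with quantized
heights (to exercise tie-breaking), plus the saddle-splitting case.

## Known limitations

* The winter scene must separate the scaffolds: trees whose limbs
  interlock in the leaf-off scene merge into one hull and are segmented as
  one crown.
* Crown area at the rim is threshold-limited: canopy below the local
  adaptive threshold (low skirts, drooping outer branches) is excluded,
  biasing CPA slightly low, while surface smoothing biases it high; the
  two partially cancel but neither is zero.
* Heavily overlapping neighbours are split along the height saddle, which
  is not necessarily the botanical boundary.
* `W1`/`W2` assume straight planting rows (a single `row_angle` per
  scene).
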