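---
title: "Segmenting and tracking T cells in calcium-indicator time-lapse imagery"
author: "phasetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and tracking T cells in calcium-indicator time-lapse imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasetrack)
```

# The problem

Migrating T cells imaged by phase-contrast microscopy are small
(roughly 8–30 px in diameter at typical magnifications), low-contrast, and
move over a background whose illumination varies slowly across the field of
view. Cells expressing a genetically encoded calcium indicator additionally
produce transient whole-cell fluorescence "flashes" when calcium
release-activated calcium (CRAC) channels open. Quantifying migration and
channel activation requires, per frame: finding every cell, measuring its
morphology and intensity, discarding detections that are not cells of
interest, and linking detections across frames into identity-preserving
tracks.

`phasetrack` implements this pipeline end to end, together with a seeded
synthetic scene generator that renders time-lapses from known ground truth,
so every stage can be scored quantitatively without any external imagery.

# Pipeline stages and their models

## Contrast enhancement

`stretchContrast()` maps intensities so that a fraction *s* (default 0.01)
of pixels saturates at each end of the bit range: the *s* and (1 − *s*)
quantiles of the frame (order statistics with linear interpolation) are
mapped linearly onto the full range, with clipping outside. The map is
monotone, applied per frame (each frame is an independent exposure), and a
constant frame passes through unchanged with a warning rather than an
error, so one blank time point cannot abort a batch run.

One consequence worth knowing: when the foreground occupies *less* than the
saturation fraction of the frame (a nearly empty field of view), the upper
quantile falls inside the background noise and the stretch amplifies noise
across the whole range. For such sparse fields either lower the saturation
fraction or segment the raw frame; the package's own sparse-field tests do
the latter.

## Tiled constrained thresholding

The frame is divided into 32 × 32 px tiles (slightly larger than a typical
cell), each thresholded independently by maximizing the between-class
variance of its histogram (Otsu's criterion). Per-tile thresholds absorb
slowly varying illumination: a linear ramp worth 30 % of the cell contrast
costs essentially no recall because each tile sees a locally flat
background.

Numerical conventions, fixed once and used by both the implementation and
its exhaustive-scan test oracle:

* candidate splits are evaluated between consecutive distinct intensity
  values; on ties the smallest split wins;
* the *reported* threshold is the midpoint between the largest background
  value and the smallest foreground value of the chosen split, so it
  separates the classes strictly;
* the mask keeps pixels strictly above the threshold;
* tiles with a single distinct value are cell-free by construction.

A tile containing no cell still produces a threshold — one that sits inside
the background noise. The *threshold constraints* reject such tiles: a tile
whose normalized threshold falls outside `thresholdBounds` is declared
cell-free and contributes nothing. The static default is `[0.08, 0.95]`,
but a fixed lower bound cannot suit both 8-bit and enhanced 16-bit data,
where the stretched background sits near 0.2 of the range. With
`autoThresholdBounds = TRUE` (the default) the lower bound is derived per
frame as

> (median + 1.5 × MAD) / (2^bits − 1),

using the whole frame's median and median absolute deviation as robust
estimates of the background level and noise. This was calibrated
empirically on rendered scenes: background-only tiles threshold within
about one MAD of the median, while tiles containing a cell of at least
8× noise contrast threshold several MADs above. It plays the role of the
"experimentally determined" constraint a microscopist would set for their
own instrument, and explicit bounds always override it.

## Circle seeding

Before tiling, a gradient circular Hough transform proposes seeds for
bright, approximately circular objects: edge pixels (Sobel magnitude above
a quarter of the frame maximum) vote one radius along their gradient
direction; the accumulator is box-smoothed and normalized by circumference
so the response is the fraction of the rim voting coherently (threshold
`circleSensitivity`, default 0.33); non-maximum suppression enforces a
minimum seed spacing of `rMin`. A seed that lands inside a thresholded
component is absorbed by it; an unabsorbed seed triggers a local
re-threshold in a (2r + 2)-square window. On well-contrasted scenes the
tiled pass finds everything and seeds are almost all absorbed; the seeding
mainly adds robustness for cells whose tile statistics are unusual.

## Components, tile boundaries and deduplication

Connected components are 8-connected (so diagonally touching pixels join),
retained when their area lies within `[minComponentArea,
maxComponentArea]`. The defaults (75–450 px) mirror the area range observed
for segmented T cells; when the expected radius range `[rmin, rmax]` is
known, the bounds `[0.6 π rmin², 1.3 π rmax²]` are the recommended
configuration and are what the package's own acceptance runs use.

Cells lying on a tile edge are found as fragments (or missed) by the
per-tile pass. `resolveBoundaries()` handles them in three steps:

1. fragments whose pixel sets touch across a tile line are fused (they are
   one object split only by the tiling);
2. every detection whose bounding box comes within `boundaryMargin` of an
   interior tile line triggers re-thresholding of a tile-sized window
   centered on that line — a shifted focal point that sees the whole cell;
   window components that touch the window edge are discarded (they belong
   to neighbours only partially covered, which keep their first-pass
   records);
3. first-pass detections overlapping a window's findings are replaced by
   them, and finally any two detections sharing a pixel are reduced to the
   larger one.

During the tiled pass the area floor is internally relaxed to a quarter of
`minComponentArea` so that sub-threshold fragments of a straddling cell can
still trigger step 2; the configured bounds are enforced after resolution.

## Feature extraction

For each detection, `computeRegionFeatures()` reports the measure set used
for downstream analysis: centroid (unweighted pixel mean, 0-based
coordinates), area, extent (area over bounding-box area), perimeter,
ellipse axes, eccentricity, and max/mean intensity over the pixel set of
the enhanced frame.

Two definitions deserve explicit record:

* **Axes and eccentricity** come from the ellipse with the same normalized
  second central moments as the region, including the per-pixel 1/12
  variance of a unit square (the regionprops convention). The correction
  keeps eccentricity strictly below 1 even for a one-pixel-wide run and
  makes axis lengths meaningful for small regions. Feret ("caliper")
  diameters would be an alternative reading of "longest distance across
  the cell"; moment axes were chosen because they are the field's standard
  meaning, are stable on digital shapes, and define eccentricity
  consistently from the same ellipse.
* **Perimeter** is the length of the outer contour traced with
  Moore-neighbor tracing, orthogonal steps counting 1 and diagonal steps
  √2. On digital disks this measure sits a few percent above 2πr (it
  follows the jagged digital rim), which is acceptable and, importantly,
  consistent between implementation and oracle. Holes in a region are not
  traced; masks produced by thresholding compact cells essentially never
  have holes.

Intensity statistics are computed on the frame that was segmented (the
enhanced frame). If raw-frame statistics are wanted, segment the raw frame
or recompute features against it.

## Filtering

`filterCriteria()` turns the domain expert's judgement into declarative
closed intervals over any subset of the features, plus an optional
activation requirement (minimum peak intensity; the default floor is the
frame's modal intensity plus three robust noise scales — a cell that never
rises above background noise shows no calcium activity). `applyFilter()`
partitions detections into kept and discarded, preserving order;
`eraseCells()` resets the discarded pixels to a background value (default:
the frame's modal intensity) on a copy, so re-segmentation no longer finds
them.

## Tracking

Detections of consecutive frames are linked by a gated minimum-cost
assignment: the cost of a link is the centroid distance plus weighted
normalized feature differences (relative area, mean intensity over the bit
range, relative major axis; default weights 1, 1, 0.5), and pairs farther
apart than `gateRadius` (default 20 px, consistent with the largest
per-step displacements of motile T cells) are inadmissible. The assignment
is solved *optimally* (shortest augmenting path / Hungarian method), not
greedily: among assignments with the most admissible links, the cheapest
is chosen. Optimality makes the tracker deterministic and lets small
problems be verified against brute-force enumeration.

`buildTracks()` iterates the linker through time: unmatched detections
start new tracks (cells entering the field of view), a track missed for up
to `maxMissedFrames` frames (default 2) may re-link within a gate enlarged
proportionally to the gap, and longer absences terminate the track (cells
leaving). No motion model is used — the cost already has its minimum at
zero displacement, which is exactly the right prior for cells that park
for long stretches.

## Summaries

`summarizeFeatures()` pools all (cell, time point) records — not per-track
means — and reports min/mean/max and the sample (n − 1) standard deviation
per measure. The `distance` measure (per-step centroid displacement) is
only defined for tracked input; datasets of immobilized cells omit it and
report eccentricity instead.

# The synthetic scene generator

`sceneConfig()`/`generateScene()`/`renderTimeLapse()` simulate the
phenomenology the pipeline must cope with, not the optics:

* cells are anti-aliased disks of radius 5–12 px (uniform), additive
  contrast 4000 over a background of 6000 on a 16-bit scale;
* additive Gaussian noise with sd 500 — contrast is 8× noise, a
  well-exposed but not trivial acquisition;
* Brownian motility of 1.5 px/frame, optional drift;
* whole-cell flashes: per cell-frame Bernoulli events (default
  probability 0.02) multiplying the disk height by `flashGain` (1.8),
  emulating calcium-indicator transients;
* an optional linear illumination ramp, parametrized as a fraction of the
  cell contrast spanned left to right — the units in which robustness is
  usually asked about ("a ramp worth 30 % of cell contrast");
* optional scripted field-of-view crossings: entering cells follow a
  linear inward path (4 px/frame, with tangential diffusion only) crossing
  the border at a scheduled frame, leaving cells the reverse; their roles
  are recorded in the truth table. Cells outside the border stay in the
  truth table with out-of-bounds centers rather than vanishing.

Default sizes (512 × 512, 60 frames, 25 cells) keep a full tracked scene
within tens of seconds of CPU time while leaving cells dense enough that
occasional contacts occur.

What the generator deliberately does **not** emulate: the phase-contrast
halo, point-spread blur, photobleaching, cell deformation during crawling,
division, and cell–cell adhesion dynamics. Passing the package's
ground-truth tests therefore demonstrates the correctness of the
algorithms under the stated noise/contrast/motility model, not performance
on any particular microscope's data; on real data the configuration
surface (saturation fraction, threshold bounds, area bounds, gate radius)
is the intended adaptation mechanism.

Ground truth is scored with `scoreDetections()` (one-to-one optimal
matching of centroids within 3 px; precision, recall, matched RMSE) and
`scoreLinks()` (fraction of consecutive-frame ground-truth identity links
reproduced by the tracks). For cells partially outside the field of view
the truth-matching gate grows to 0.6 × radius, because a truncated disk's
centroid is biased inward by up to about half a radius — this affects only
the scoring of border-crossing cells, never the pipeline itself.

# Numerical and degenerate-input decisions

* Quantiles: type-7 order statistics with linear interpolation, everywhere.
* Rounding of rendered/enhanced intensities: `floor(x + 0.5)` (half always
  up), so results are platform-independent.
* Otsu ties: smallest variance-maximizing split; reported threshold is the
  class midpoint (see above).
* Assignment ties: the solver is deterministic for a fixed input order;
  detections are ordered by centroid scan order, so identical inputs give
  identical tracks.
* Degenerate inputs: constant frames pass enhancement unchanged (warning);
  single-valued tiles are cell-free; empty detection lists are legal
  everywhere (empty CSVs keep their header); an empty time-lapse cannot be
  constructed.
* Scene generation rejects configurations too dense to place cells at
  pairwise separation ≥ 2 × max radius within a bounded number of
  attempts, with advice to lower the density.

# Known limitations

* Cells in contact fuse into one component; there is no watershed-style
  splitting beyond the circle-seed mechanism. In the default synthetic
  conditions this costs a few percent of detections in crowded frames and
  is the main driver of tracking-link loss.
* The per-tile threshold assumes cells are *bright* relative to their
  local background (fluorescence-like contrast, as rendered by the
  generator); dark-on-bright phase-contrast cells would need an inverted
  frame.
* The enhancement's fixed saturation fraction misbehaves on nearly empty
  fields (see above).
* Tracks have no lineage: divisions and merges are out of scope for
  T cells on imaging timescales.

# Problem sizes used by the tests

The test suite and the acceptance script size their simulations to run on
one CPU in a few minutes: feature and threshold oracles use hundreds of
random regions/tiles; still-scene detection uses 512 × 512 frames with 40
cells (ten scenes in the tests, six in the script, each with a ramped
twin); boundary deduplication uses twenty 128 × 128 single-cell scenes;
tracking uses 60-frame, 25-cell scenes (five in the tests, two in the
script); link optimality is checked against brute-force enumeration on 500
random problems of up to 6 × 6.

# A short example

```{r example, eval = FALSE}
cfg <- sceneConfig(nFrames = 10, nCells = 15, seed = 7)
sc  <- generateScene(cfg)
rn  <- renderTimeLapse(sc)

enh   <- enhanceTimeLapse(rn$timelapse)
segC  <- segmentationConfig(minComponentArea = 47, maxComponentArea = 589)
dets  <- segmentTimeLapse(enh, segC)
tracks <- buildTracks(dets)

scoreDetections(sc, dets)
scoreLinks(sc, tracks)$linkAccuracy
summarizeFeatures(tracks)
```
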