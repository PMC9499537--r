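---
title: "Quantifying apoptosis-triggered ERK waves and node patterning in organoid monolayers"
author: "erkwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying apoptosis-triggered ERK waves and node patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological system and the measurement problem

Human colonic organoid monolayers self-organize into regularly spaced,
densely packed crypt-like compartments ("nodes") of proliferative cells,
surrounded by sparser differentiated cells. Apoptotic extrusion events —
which occur preferentially outside nodes — launch radially propagating
waves of ERK kinase activity. Cells in the path of a wave transiently
activate ERK and migrate toward the dying cell. The spacing of nodes is
comparable to the diameter of these waves, which suggests the waves set the
tissue's length scale.

`erkwave` implements the quantitative pipeline needed to study this system
in time-lapse fluorescence imaging:

* nuclear segmentation from an H2B channel, and per-cell ERK activity from
  a kinase translocation reporter (KTR) measured as the ratio of mean
  cytoplasmic (two-pixel perinuclear annulus) to mean nuclear intensity
  (`segmentNuclei()`, `makeAnnulus()`, `measureKTR()`);
* optimal frame-to-frame tracking (`linkTracks()`) and apoptotic event
  detection from a caspase channel (`detectApoptosisEvents()`);
* apoptosis-referenced movement statistics, distance-ordered kymographs and
  wave speed/extent/duration estimation (`computeDNuc()`, `computeMov()`,
  `buildKymograph()`, `estimateWave()`, `crossCorrErkMovement()`);
* DBSCAN clustering of ERK-active cells, cumulative activity heat maps,
  node detection, spacing statistics, compartment assignment and per-cell
  intensity quantification (`clusterErkActive()`, `erkActivityHeatmap()`,
  `detectNodes()`, `assignCompartments()`, `quantifyChannelPerCell()`,
  `nearestNucleiDistances()`, `localizeEvents()`);
* particle image velocimetry of collective flow (`pivPair()`, `pivStack()`,
  `convergenceToward()`).

Because no raw imaging is distributed with the study this package is built
around, every estimator is validated in closed loop against an agent-based
synthetic monolayer (`simConfig()`, `simulateMonolayer()`,
`renderFrameStack()`) whose ground truth is known exactly.

## The synthetic monolayer model

A simulation is parameterised by a `SimConfig`. All lengths are in
micrometres, times in minutes, densities in cells per 100x100 um tile.

**Geometry.** Node centres are laid on a jittered square grid whose
constant equals `nodeSpacingMean` (default 399 um, the observed mean
distance between neighbouring proliferative compartments), with disk radius
`nodeRadius` (80 um). Cells are dart-thrown at `nodeDensity` (40) inside
nodes and `nonnodeDensity` (10) outside, with a hard minimum inter-nucleus
spacing of 1.5 nuclear radii (`nucleusRadius` = 6 um).

**Apoptosis.** Events arrive at `apoptosisRate` per frame and strike a
non-node cell with probability `pNonnode` (0.8, matching the observed
non-node bias of caspase-positive cells). The dying cell is extruded: it is
removed from the ground truth after its event frame and rendered as a
shrinking nuclear remnant for two frames, giving trackers a realistic
termination signature.

**Trigger wave.** An event at time `t_a` activates a cell at distance `d`
(measured at the event frame) at onset `t_a + d/v` with duration
`D(d) = D0 (1 - d/R_max)^alpha_D` and amplitude
`A(d) = A0 (1 - d/R_max)^alpha_A`; cells beyond `R_max` never activate.
Defaults: `v` = 4.7 um/min, `R_max` = 450 um, `D0` = 40 min, `A0` = 1,
both taper exponents 1 (a linear dissipation of duration and intensity
with distance, the simplest shape consistent with the roughly linear decay
seen in the source data). Overlapping waves combine by the maximum, not the
sum — waves are rare enough at the default event rate that overlap hardly
occurs, and the max rule is idempotent.

**Motion.** At the event frame, cells within `recoilRadius` (25 um) of the
dying cell are displaced outward by `recoilDistance` (2 um; the magnitude
of the initial recoil is not quantified anywhere we know of, so this
default is an order-of-magnitude guess and is flagged as such here). While
activated, a cell drifts toward the nearest active event site at
`migrationGain * E` um/min (default gain 0.5). Isotropic Gaussian jitter
(`jitterSd` = 0.15 um per axis per frame) is added everywhere, and nuclei
are pushed apart so no pair ends closer than one nuclear radius.

**Rendering.** The half-maximum radius of each H2B nucleus equals the
nuclear radius: nuclei are drawn as uniform disks with a one-pixel
anti-aliased edge, i.e. sharp-edged objects seen through a point-spread
function. This matters: a threshold segmentation then recovers the true
nuclear pixel set, so the measured C/N ratio is an unbiased readout of the
rendered one. The KTR channel draws, per cell, a cytoplasmic disk and a
nuclear disk whose mean intensities encode the true ratio
`C/N(E) = cnBaseline * (1 + (g - 1) E)` with `cnBaseline` = 0.85 (inactive
cells are nuclear-enriched) and `g = ktrPartition` (default 2), so the C/N
fold-change between E = 0 and E = 1 equals `g` exactly. A caspase spot
marks each event for two frames. Gaussian noise of sd `noiseSd` (default
0.01 against a signal scale of 0.35-1) is added to all channels.

Calibration defaults are 1.3 um/px and 5 min/frame; 5-minute sampling
resolves a 4.7 um/min front at this pixel size. Frames are 1-based in R;
frame `f` occurs at `(f - 1) * frameInterval` minutes, and pixel centres
map to micrometres as `x = (col - 0.5) * pixelSize`.

What the simulator deliberately does *not* emulate: mechanical coupling
between neighbours (only wave-activated cells move; in real tissue,
passive neighbours are dragged along), out-of-focus light, illumination
gradients, photobleaching, mitosis, and any Wnt/ERK biochemistry. The
phorbol-ester, MEK-inhibition and EGFR-inhibition regimes are pure
parameter presets (`globalErk = "on"`, `"off"`, `migrationGain = 0`), not
signalling models. Passing tests therefore demonstrate correctness of the
estimators under idealised image formation, not robustness to every
artifact of real microscopy.

## Measurement choices

**Segmentation.** Gaussian smoothing (sigma 0.5 px), Otsu threshold, and a
watershed on the exact Euclidean distance transform to split touching
nuclei; objects under 15 px are discarded and border-touching nuclei are
kept but flagged. The in-house tool the source study used is not described
beyond its inputs, so this standard, parameter-light chain stands in for
it.

**Annulus.** The cytoplasmic mask of a nucleus is the set of background
pixels within Euclidean distance 2 px of it, excluding every nuclear pixel
and every pixel within 1 px of *another* nucleus. Distances are computed
between pixel centres with an exact distance transform, so the mask equals
a brute-force enumeration pixel for pixel (and is tested against one).
Whether annulus pixels overlapping a *neighbour's cytoplasm* should also be
excluded cannot be decided from image data; only neighbouring nuclei are
excluded, and the residual cytoplasm mixing is an acknowledged ambiguity.
A cell is called ERK-active when its annulus mean strictly exceeds its
nuclear mean; an exact tie is inactive.

**Tracking.** Frame-to-frame linking minimises total squared displacement
by the Hungarian algorithm under a hard gating radius (15 um), decomposed
over connected components of the gating graph. Unmatched detections start
tracks; tracks missing for more than `maxGap` = 2 frames terminate; gap
frames are linearly interpolated and flagged. Divisions are not modelled
(a daughter starts a new track). On small instances the assignment is
tested against brute-force enumeration over all permutations.

**Wave estimation.** Tracks are binned by their distance to the event at
the event frame (25 um bins). A bin's onset is the first post-event frame
that is "crossed", where a frame is crossed when either

1. the bin's mean C/N exceeds its pre-event baseline (6 frames) by
   `max(k * sd, relFloor * baseline)` with `k = 3` and `relFloor = 0.01`,
   or
2. at least `minActiveCells = 2` individual cells exceed their own
   baselines by `max(kCell * pooled sd, relFloor * baseline)`.

The second criterion exists because of a sampling property of tapering
trigger waves: near the maximal radius the activation duration drops below
one frame interval, so at any one frame only a thin annulus of staggered
cells is caught active and the bin mean barely moves, even though the
sampled cells individually show the full local amplitude. Without it the
detected extent systematically stops one to two bins short of the true
front. Three safeguards keep these criteria honest under noise, where both
were observed to misfire: the bin-mean sd is floored by a globally pooled
per-cell estimate scaled by bin size (6-frame per-bin estimates are too
unstable); cells already "hot" during their own baseline are excluded from
the count (measurement noise is heavy-tailed because masks re-quantise
under positional jitter); and an outward monotonicity gate discards any
crossing earlier than the latest onset accepted at a smaller distance — a
front cannot reach an outer bin before an inner one. The 1% floor sits
roughly three times above the bin-mean fluctuation observed on noiseless
renders (~0.3%, from mask re-quantisation alone) and below the smallest
per-bin signal at the outermost detectable bin. Border-flagged nuclei are
excluded altogether; their annuli are truncated by the field of view.

The onset-bin run is grown outward from the innermost detected bin,
tolerating a single undetected bin; the extent is the run's largest bin
centre, the speed the least-squares slope of bin centre on onset time, and
the total duration the last onset plus that bin's active time. Because the
printed speed of the exemplar wave is a distance/period ratio,
`extent / totalDuration` is also reported (`speedExtentDuration`) so both
conventions can be compared. Whether a printed maximal distance refers to
front position at last detection or to cell-activity extent is ambiguous;
the estimator reports the largest bin with detected activity onset.

**Cross-correlation.** Per cell, Pearson correlation between the C/N series
and the frame-to-frame movement series at every lag up to `maxLag`; ties
in the peak break toward the smaller absolute lag, which is conservative
with respect to the claim that ERK precedes movement.

**Node detection.** A binned (10 um grid) Gaussian kernel density
(bandwidth 40 um) of nuclear centroids, thresholded by Otsu floored at 1.5
times the background median (estimated from the lower quartiles, which stay
uncontaminated even when nodes cover a third of the field). Node existence
additionally requires some tile to beat a complete-spatial-randomness
null — under CSR a KDE tile has mean `lambda` and sd
`sqrt(lambda / (4 pi sigma_t^2))`, and a sparse uniform field is
intrinsically clumpy at a 40 um bandwidth, so without this test phantom
nodes appear. The existence test does not participate in the segmentation
threshold, so genuine node areas are not eroded by it.
Node spacing is the nearest-neighbour distance between node centroids
(the most natural reading of "spacing"; an edge-to-edge definition would
differ by about one node diameter). Compartment assignment is a label-grid
lookup, deterministic and total.

**Active-region geometry.** Clusters of ERK-active centroids come from an
in-package DBSCAN (`eps` defaults to 1.5x the frame's median
nearest-nuclei distance, `minPts` = 5); a cluster's spatial region is the
union of eps-radius disks around its member centroids rasterised on the
pixel grid, with boundaries extracted by contour tracing. This disk-union
construction covers concave clusters like an alpha-shape would, while
staying exactly testable against per-pixel brute force; the cumulative
heat map is the per-pixel count of frames whose active region contains the
pixel.

**PIV.** Single-pass windowed zero-normalised cross-correlation (32 px
windows, 50% overlap, search to half a window), with the correlation at
each displacement computed over the true overlap region, sub-pixel
refinement by a three-point Gaussian fit, and validity gated on the peak
correlation (>= 0.5). ZNCC rather than plain covariance matters on nuclear
imagery: un-normalised peaks lock onto whichever group of nuclei is
largest, and known-shift recovery degrades several-fold. Convergence
toward an event is the mean projection of valid vectors onto the unit
vector pointing at the event. PIV reports the *modal* displacement of a
window, so in mixed windows of movers and non-movers it underestimates the
mean flow; the flow fixtures are therefore confluent (density 30) with
strong wave-directed migration (gain 1 um/min), emulating the clearly
visible collective flow of the imaging experiment these analyses mirror.

## Named fixtures and problem sizes

`makeFixtures()` provides the validation scenarios used by the test suite
and by `scripts/acceptance.R`:

* `fig3`: one apoptotic event in the centre of a 960x960 um non-node field
  of ~455 cells, wave at 4.7 um/min to 450 um, noiseless, 28 frames. Used
  for speed/extent recovery and the exact `Mov = 0` identity.
* `fig1`: a 2000x2000 um patterned monolayer (25 nodes at 399 um spacing,
  4x density contrast, ~5,500 cells, one frame) for node detection and
  spacing.
* `fig4_pma` / `fig6_meki`: global-activation (uniform, E = 1) and
  ERK-off (enlarged nodes) regimes for direction-of-effect checks.
* `piv_wave` / `piv_gefitinib`: dense 420x420 um fields with one central
  event, with and without wave-directed migration, for flow analysis.

These sizes keep a full closed-loop run (simulate, render, segment, track,
estimate) around a minute per movie on one core while leaving every
distance bin well populated; the ten-event extent ensemble is the largest
computation in the suite.

## Known limitations

* The wave-extent estimator's resolution is one distance bin by
  construction, and with linearly tapering duration the outermost ~5% of
  the wave is unobservable at any realistic frame interval; recovered
  extents sit half a bin to one bin inside the configured radius.
* The KTR round trip is exact only while nuclei are well segmented; heavy
  crowding (merged nuclei) biases the C/N ratio toward 1.
* PIV convergence underestimates mean tissue flow wherever windows mix
  moving and stationary cells.
* The event detector assumes caspase spots are bright and sparse; two
  events closer than `epsUm` within `maxFrameGap` frames merge.
* No mitosis: a division appears as a track birth, and sustained imaging
  of proliferative nodes would accumulate such births.
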