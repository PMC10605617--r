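---
title: "Quantifying renal microvascular structure from microbubble tracks and micro-CT casts"
author: "ulmvasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying renal microvascular structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulmvasc)
```

## The problem

Microvascular rarefaction — the loss of small vessels — and increased
vessel tortuosity accompany the development of diabetic kidney disease.
Ultrasound localization microscopy (ULM, also called super-resolution
ultrasound) can resolve vessels far below the acoustic diffraction
limit by localizing individual intravascular microbubbles over many
frames and linking their positions into trajectories, which act as
surrogates for vessel centerlines. `ulmvasc` implements the in vivo
processing chain (detection → motion correction → trajectory linking →
accumulation → structural read-outs) together with the companion ex
vivo micro-CT branch used to validate density read-outs on
contrast-perfused kidney casts, and a synthetic-scene generator that
provides ground truth for every stage.

## The ULM processing model

**Detection and localization.** Each contrast frame is scanned for
local maxima above a relative threshold (default 0.3 of the frame
maximum), with non-maximum suppression inside a minimum separation
(default 0.2 mm) and an absolute amplitude floor for frames that
contain no bubble (a frame maximum of pure noise would otherwise make
the relative threshold meaningless). Surviving peaks are refined by an
intensity-weighted centroid. The centroid window is configurable: the
class default is the classical 5 × 5 px window, while the pipeline
configuration uses a window matched to the point-spread function
(15 px at the default PSF σ of 0.15 mm on 0.05 mm pixels), because a
window that truncates the PSF shrinks the centroid towards the peak
pixel and costs localization accuracy.

**Motion correction.** Tissue motion under ventilation is modeled as a
global rigid translation per frame. It is estimated on the interleaved
B-mode frames by block matching: a 3 × 3 grid of blocks (default
1.5 mm) from a reference frame (default the first frame; the choice is
configurable) is matched against each frame by normalized
cross-correlation, the integer peak is refined by separable parabolic
interpolation, and blocks with peak correlation below 0.5 are dropped
from the average — if all blocks fall below 0.5 the frame is flagged
through the confidence slot. Because ventilation is slow relative to
the 55 Hz frame rate, each frame's search is a ±3 px window centred on
the neighbouring frame's displacement, falling back to the full search
radius when confidence is low; displacements beyond the search radius
clip at the boundary, which is the documented failure mode. Bubble
positions are corrected by subtracting the displacement of their frame
(B-mode and contrast frames are interleaved 1:1, so the mapping is
direct).

**Hierarchical Kalman linking.** Each open track carries a 2D
constant-velocity Kalman state; velocity is born at zero with a
covariance inflated to the gate speed, so a newborn track can follow
any admissible flow direction. Frame by frame, predicted positions are
matched one-to-one to detections by a maximum-cardinality,
minimum-total-distance assignment under a gate (Hungarian method on an
augmented matrix; `solveAssignment()`), with the gate defaulting to
`maxSpeed / frameRate` (20 mm/s at 55 Hz ≈ 0.36 mm). Unmatched tracks
close immediately — no gap tolerance, so tracks span strictly
consecutive frames — and unmatched detections open new candidates. The
"hierarchy" is a multi-pass scheme: detections consumed by accepted
tracks are removed and the remainder is re-linked with the gate
widened (default two passes, scale 2). Only tracks observed in at
least three consecutive frames are kept; this minimum-track-length
rule is exact and is tested as such. Emitted tracks store the measured
(motion-corrected) positions rather than the filtered states, so the
read-outs quantify what was observed, and ties in emission order are
broken by birth frame and then lateral position for deterministic
output.

**Accumulation.** Tracks are accumulated on a super-resolution grid
(default 25 µm — fine enough that sub-75 µm vessels remain resolvable)
by exact supercover rasterization of every inter-point segment: a
pixel is track-filled if any segment passes through it. A direction
map stores the per-pixel circular mean of segment angles; it is used
only for the color-wheel rendering (`writeSrusPng()`), never for
quantification.

## Structural read-outs

**Patch density.** Within a region of interest (cortex CO, outer
medulla OM, inner medulla IM — supplied as a label mask), square
patches of 2 × 2 mm² with 50% overlap tile the region's bounding box.
A patch is retained only if at least half of its pixels carry the
region label, and its density is the fraction of its *region* pixels
that are track-filled — zero to one, with one meaning a patch
completely covered by tracks. The regional summary is the arithmetic
mean over retained patches, expressed in percent. Anchoring the patch
grid at the region bounding box and using region pixels as the
denominator makes the value independent of how much background a
border patch sees; both choices were open in the protocol this
mirrors and are fixed here as stated. Densities are counted on the
super-resolution grid.

**Tortuosity.** Per track, the distance metric: actual path length
divided by the straight start-to-end distance; 1 for a straight
vessel, growing without bound with meandering. Tracks whose chord is
shorter than one grid pixel (loops) are excluded and tallied. A track
is attributed to the region holding the majority of its points, ties
going to the first point's region. The sum-of-angles metric is
provided (`sumOfAnglesTortuosity()`) as a clearly secondary
alternative discussed in the tortuosity literature; the distance
metric is the primary read-out.

## The micro-CT branch

Kidney casts are processed in five steps. (1) `segmentKidney()`:
26-connected region growing from a seed above an intensity threshold,
followed by a morphological closing with a Euclidean ball (default
radius 2 voxels) standing in for the manual smoothing of the hilum.
(2) `interpolateLabels()`: sparse manual region annotations (about
every fifth coronal slice) are densified by shape-based interpolation —
per label, the 2D signed distance fields of the nearest annotated
slices are linearly interpolated along the slice axis and thresholded
at zero; annotated slices are reproduced exactly. The cortex mask is
the exact set difference kidney ∖ medulla (`RegionMasks3D()` enforces
this). (3) `segmentVessels()`: plain intensity thresholding inside the
kidney mask, with the threshold a required explicit argument because
the protocol tunes it per scan. (4) `estimateLocalRadius()`: local
thickness — for every vessel voxel, the radius of the largest sphere
fully inside the segmentation that contains it — computed as an exact
Euclidean distance transform followed by descending-radius sphere
propagation. Distances are voxel-center-to-voxel-center with no
half-voxel surface correction, matching the convention of the porous
media tooling this read-out mirrors; a straight cylinder of nominal
radius r therefore reads about r − 0.5 voxels. (5)
`partitionByRadius()` and `computeRegionDensity()`: thresholding the
radius map at 10 voxels (cortex) and 6 voxels (medulla) splits small
from large vessels, and regional density is small-vessel voxels over
region voxels *after removing large-vessel voxels from the
denominator* — removing them from both numerator and denominator is
the only reading that keeps the value "small-vessel fraction of the
remaining tissue". The radius thresholds are kept in voxel units,
which are treated as authoritative; the medullary read-out uses the
combined inner + outer medulla mask. Micro-CT intensity volumes use
the protocol's 26.5 µm isotropic voxels by default.

## The synthetic-scene generator

`generateVesselTree()` builds quasi-planar dichotomously branching
trees: roots enter from the shallow edge and run toward depth,
children attach exactly on their parent's endpoint, and every
segment's centerline is a straight chord plus an optional sinusoidal
perpendicular perturbation whose arc length — hence tortuosity — is
analytically known. Vessel count controls density; the sine amplitude
controls tortuosity (ground truth of a straight segment is exactly 1
and is non-decreasing in the amplitude). `subsetVesselTree()` removes
whole root lineages to emulate rarefaction without breaking
connectivity.

`simulateMbMovie()` advects bubbles as plug flow along centerlines —
no radial position and no Brownian jitter, the simplest model that
exercises the tracker, consistent with treating trajectories as vessel
surrogates. Bubbles enter as a Poisson process (rate in bubbles/s over
the whole field, an explicitly free parameter since in vivo bubble
concentration in a field of view is not standardized), thinned so that
two bubbles never enter the same vessel within `minEntryGap` (default
0.1 s): microvessels carry bubbles in single file, and a pair riding
one centerline within a PSF width would be both unphysical and
unresolvable by any localizer. Frames render each bubble as an
isotropic Gaussian (σ default 0.15 mm; the true transducer PSF at
10 MHz is hardware-specific and out of scope) plus i.i.d. Gaussian
noise on an arbitrary [0, 1] intensity scale — detection thresholds
are relative for exactly this reason. A global sinusoidal translation
(default 0.2 mm at 1.2 s period, mostly axial) displaces contrast and
B-mode alike; the B-mode texture is an analytic Gaussian-spot speckle
field re-rendered under each frame's shift so that sub-pixel motion is
exact. Acquisition defaults mirror the targeted protocol: 55 Hz frame
rate, 10 MHz center frequency and mechanical index 0.1 recorded as
metadata only. Everything the simulator does — exact positions,
trajectories, injected motion, per-segment tortuosity — is returned as
a `GroundTruth` object, and every generator is a pure function of its
arguments including the seed.

`renderUctVolume()` voxelizes 3D trees as capless finite cylinders
(with spheres at interior polyline joints), so a straight vessel has
the analytic cylinder volume; the exact per-voxel tube radius is
emitted alongside as ground truth.

What the generator does *not* emulate: acoustic wave propagation and
amplitude-modulation pulse physics, out-of-plane bubble motion,
non-rigid tissue deformation, radial flow profiles, and vessel-wall
signal. Passing the recovery tests therefore demonstrates the
correctness of the processing chain under its stated model, not
end-to-end performance on scanner data.

## Numerical choices and degenerate inputs

* Assignment semantics: maximum-cardinality gated matching with
  minimum total distance; verified against exhaustive enumeration on
  small instances in the test suite.
* All-zero or bubble-free frames yield empty detection lists, never
  errors; empty track sets yield empty rasters, zero density and an
  empty (NA-mean) tortuosity table.
* A patch set in which no patch reaches 50% region coverage returns an
  empty result with a warning; a region absent from the mask is an
  error.
* Distance transforms are exact (squared-distance lower-envelope
  method); the array border behaves as if structures continued beyond
  it, so cylinders touching the volume faces behave as infinite tubes.
* The supercover line rasterizer bounds its traversal by the exact
  number of boundary crossings, so endpoints lying exactly on pixel
  edges cannot cause runaway walks; points exactly on an edge are
  knife-edge cases in which a translated replay may differ by one
  pixel.
* Reported CSV floats carry 6 significant digits with fixed column
  order; identical configuration and seed give byte-identical outputs,
  and every run writes its resolved configuration with an md5 content
  hash next to its outputs.

## Study conditions used by the tests and the acceptance script

Recovery experiments run at desk scale: 250-frame (≈4.5 s) movies over
a 12.8 × 12.8 mm field with 10–12 unbranched root vessels for tracking
and rarefaction, 150-frame movies for the tortuosity contrast, and
40–60-frame movies for determinism and motion checks; micro-CT
phantoms use 40 × 40 × 60-voxel cylinders and ≈190³-voxel synthetic
casts. In the rarefaction experiment the bubble influx scales with the
number of vessels — the same infusion distributed over fewer vessels —
so that per-vessel bubble statistics, not bubble starvation, carry the
density contrast. Tracking recall and precision are scored at track
level: an emitted track is correct when at least 80% of its points
match one ground-truth bubble within one pixel, and a true track
(observed ≥ 3 frames) is recovered when at least one correct emitted
track points to it, so honest fragmentation counts toward recall while
identity switches lower precision.

## Known limitations

* Vessels that cross in the 2D plane confuse both detection (merged
  blobs within one PSF) and linking (identity switches); recall and
  precision degrade by a few percent in scenes with many crossings.
* The rigid-translation motion model cannot represent non-rigid
  deformation; residual motion folds into localization error.
* The local-thickness convention reads ≈0.5 voxel below the nominal
  radius of an ideal cylinder; radius thresholds are interpreted in
  the same convention, so partitions remain exact on phantoms, but
  absolute radii carry that bias.
* Region attribution of a track by majority of points is coarse for
  tracks that straddle a boundary for most of their length.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- defaultPipelineConfig(
  scene = list(nRootVessels = 10L, branchingDepth = 0L),
  acquisition = list(nFrames = 250L))
res <- runSrusPipeline(cfg, "srus_out")
res$summary          # per-region density %, tortuosity, track counts

uct <- runUctPipeline(defaultPipelineConfig(), "uct_out")
uct$densities        # cortex / medulla small-vessel density
```
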