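---
title: "Methods: operant arena occupancy, bouts, indices and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operant arena occupancy, bouts, indices and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyoperant)
```

## The measurement model

A single fly moves in an oblong arena whose long axis is split at a
boundary into a region of self-administration (ROSA) — presence there
triggers stimulus delivery through a port at that end — and a
non-self-administration region (NoSA) ending in a vacuum port. The
acquisition delivers the fly's centroid `(x, y)` per frame at 15 fps for a
15-minute session. Everything downstream is a function of that position
stream and the arena geometry:

* the per-frame **Boolean Occupation Score** (1 in ROSA, 0 in NoSA),
  whose mean over half-open time bins `[kb, (k+1)b)` is the binned
  occupancy score;
* **bouts**: maximal runs of region residence, the unit of stimulus
  self-administration;
* **session behaviors** (totals over the session): time in region,
  distance moved in region, maximum depth toward the port;
* **bout behaviors**: entry count, mean bout duration, mean bout distance,
  mean latency to re-enter;
* the **preference index** `PI = (t_R − t_N)/(t_R + t_N)` over the last
  seven minutes, and the **operant learning index**
  `OLI = (L − E)/(L + E)` comparing a metric's minute-14 bin to its
  minute-1 bin.

## Conventions and the reasoning behind them

**Boundary assignment.** A point exactly on the boundary belongs to NoSA by
default: the stimulus valve should not open while the fly sits on the
dividing line, so onset is conservative. The opposite convention is one
flag away (`boundary_to = "rosa"`). With the default, region membership is
exactly equivalent to strictly positive ROSA depth, which keeps the
label/depth pair internally consistent.

**Depth.** "Depth" is axis penetration: the signed distance along the long
axis from the boundary toward the region's port. In an oblong arena this is
monotone in true port proximity but insensitive to lateral wobble, which
makes the per-fly maximum a stable summary. A Euclidean variant
(`metric = "euclidean"`, port distance at the boundary minus port distance
at the point) is exposed for users who prefer straight-line proximity; the
two orderings agree along the long axis.

**Coordinates and intervals.** Image convention: origin top-left, `x` along
the long axis, `y` down; frames are 0-based; all time bins and bout
intervals are half-open `[start, end)`. The OLI's "at 14 min" and "at
1 min" are read as the 1-minute bins `[780, 840)` and `[0, 60)`: the
metrics involved are extensive (seconds, centimeters), so per-bin totals
are the only reading consistent with their units.

**Bout edge cases.** No minimum bout duration is imposed by default
(`min_bout_frames = 1`) — duration histograms legitimately contain very
short bouts, and any debouncing threshold would bias the entry count; the
knob exists for noisy trackers. A residence already in progress at frame 0
counts as a bout starting at t = 0 (excludable via `include_initial`). A
bout still open at session end is kept — the stimulus was experienced — but
contributes no latency, since its successor is undefined. With these rules,
ROSA time equals the sum of ROSA bout durations exactly, ROSA and NoSA
bouts alternate, and their counts differ by at most one.

**Distance attribution.** A step between frames is credited to the region
of its destination frame, matching occupancy onset at entry. Steps touching
invalid or imputed frames contribute zero: a held position must not
fabricate movement.

**Undefined values.** Mean bout statistics for a fly with no bouts, a PI
with zero time in both regions, or an OLI with two empty bins are `NA`,
never 0 — zeros would silently deflate group averages. `NA` rows are
dropped (and reported) before PCA.

**Gap repair.** Tracking dropouts of at most `max_gap_frames` (default 15
frames = 1 s at 15 fps) are filled by holding the last valid position and
flagging the frames imputed; longer losses stay invalid. Holding, rather
than interpolating, avoids inventing boundary crossings inside a gap. The
occupancy series inherits held values so that every frame is assigned and
region times always sum to the session duration.

**Stored occupation columns.** Acquisition CSVs may carry their own
occupation score; it is never trusted for analysis — occupancy is always
recomputed from geometry — but a disagreement on ≥ 1% of frames triggers a
warning, so hardware-ROI drift is surfaced rather than hidden.

## The tracker

The acquisition's own tracking algorithm is not part of the data files, so
the package provides a reference single-animal tracker for infrared-style
stacks: per-pixel median background over 25 evenly spaced frames (robust
as long as the fly occupies any pixel in a minority of samples), absolute
difference, Otsu threshold with a floor of 10 gray levels (the floor stops
noise-driven thresholds on fly-free frames), connected components, largest
component of at least 4 px, intensity-weighted centroid. Pixel centers sit
at `(j − 0.5, i − 0.5)`, making centroids translation-equivariant under
integer shifts. One fly per arena is assumed: multiple components keep the
largest, with no identity tracking. No claim of bit-equivalence with any
other tracker is made; accuracy is validated against the renderer's ground
truth instead (median centroid error well under 1 px at noise SD 2).

## The simulator

The synthetic-data generator is a two-state semi-Markov model: the fly
alternates ROSA and NoSA residences with independently drawn durations
(exponential by default; gamma available to probe non-memoryless latency
structure), and within each residence follows a correlated random walk
(normal turning angles with SD `1/sqrt(turn_concentration)` rad, default
0.5; truncated-normal speeds, default 1 ± 0.5 units/s) confined to the
zone. Confinement folds coordinates back into the zone box (reflection);
the box is inset by a wall margin (default 0.5 units) because a fly's body
center cannot reach a wall. `port_drift` in `[−1, 1]` adds a constant
along-axis bias toward (positive) or away from (negative) the active
zone's port, shaping the depth metric without touching the bout law. Zone
transitions place the fly one movement step across the boundary. A
zero-speed parameterization cannot execute transitions: the fly freezes
and the session is a single truncated bout, which is the physically
consistent degenerate limit.

Driving the zone process by residence times rather than by emergent
boundary crossings is deliberate: it makes bout statistics analytically
controllable, so pipeline output can be checked against known generative
values. The first zone is drawn with the stationary probability
`μ_bout/(μ_bout + μ_away)`; with exponential residences, memorylessness
then makes the expected occupancy fraction equal the stationary fraction
at any finite session length, not just asymptotically.

The valence presets encode the qualitative contrast between appetitive and
aversive stimuli — appetitive: fewer but longer self-administration bouts,
short re-entry latencies, deep port approach (mean bout 20 s, mean away
8 s, drift +0.6); aversive: frequent short bouts, long latencies, shallow
penetration (5 s / 15 s / −0.6); neutral: symmetric (10 s / 10 s / 0).
These values were fixed once when the presets were designed.

What the simulator does **not** emulate: odor-plume physics, grooming and
stops, wall-following, optogenetic dose–response, inter-fly variability in
locomotor capacity, or tracker-specific artifacts other than additive
Gaussian pixel noise. Tests passing on synthetic sessions therefore
validate the *computations* — segmentation, binning, indices, conservation
laws, tracker geometry — not any biological claim about real flies.

The renderer closes the loop for the tracker: uniform background (200 gray
levels) minus a Gaussian blob (σ = 2 px, amplitude 120) at the true
position, plus i.i.d. Gaussian noise, clamped to `[0, 255]`, with true
pixel centroids attached.

## Numerical choices

* Residence durations are drawn in seconds and quantized to whole frames
  (minimum one); at 15 fps and mean durations of several seconds the
  quantization bias is orders of magnitude below Monte-Carlo standard
  errors.
* Binned scores keep a ragged final bin and flag it `partial` rather than
  silently dropping data.
* The duration histogram uses half-open bins plus a terminal `[e_last, ∞)`
  category, so counts always sum to the bout count.
* PCA standardizes columns to z-scores (sample SD, n − 1), decomposes with
  `prcomp`, fixes each component's sign so its largest-magnitude loading
  is positive, and retains components with eigenvalue > 1 — i.e.
  components explaining more variance than one standardized variable
  (the Kaiser criterion). That operationalizes the informal "explains
  variance for more than one variable" retention rule; the choice is
  recorded in the output so consumers can re-threshold.
* T-maze death subtraction removes deaths from the recorded arm when an
  arm is given and from the DNP count otherwise — the conservative choice,
  since DNP subtraction leaves the CPI unchanged. Trials with
  participation ≤ 0.5 (inclusive) are excluded.

## Problem sizes used in validation

The test suite and the acceptance script use Monte-Carlo sizes chosen to
make 3-standard-error bands decisively narrow while keeping runs quick on
one core: 1,000 random occupancy series of 13,500 frames for segmentation
oracles; 200 random plus 600 simulated sessions for the conservation
suite; 300 sessions for parameter recovery (mean bout 8 s, mean away 12 s,
occupancy 0.4); 300 sessions per arm (150 in the acceptance script) for
the valence contrast; 50 rendered 900-frame stacks (20 in the acceptance
script) at 1 fps for tracking accuracy, with the blob kept at least 2σ
from the boundary by the simulator's wall margin so occupancy flips cannot
arise from sub-pixel error.

## Known limitations

* Depth as axis penetration differs from Euclidean port distance off-axis;
  both are exposed, only one can be the default.
* The entry count includes a session-start residence by default; datasets
  defining entries strictly as boundary crossings should pass
  `include_initial = FALSE`.
* The tracker assumes exactly one animal and high contrast; it does not
  handle occlusion by arena structure, multi-animal identity, or
  illumination drift beyond what the median background absorbs.
* Group-level inference (ANOVA, mixed-effects models, post hoc
  corrections) is intentionally out of scope; the package stops at tidy
  per-fly tables ready for any standard statistics stack.
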