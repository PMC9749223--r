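---
title: "Quantifying plate-level C. elegans behavior with wormplate"
author: "wormplate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plate-level C. elegans behavior with wormplate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormplate)
```

# Overview

`wormplate` quantifies the behavior of *C. elegans* populations crawling on
agar plates from long-term, low-magnification timelapse recordings. The
motivating application is the dauer exit decision: dauer larvae transferred
to a fresh plate progress over many hours from locomotor quiescence through
a fast, straight "dispersal" state to food-dependent dwelling, and in
parallel abandon the stiff, low-curvature dauer posture. Because single
animals enter and leave the field of view freely, all read-outs are
population averages on a common time axis of hours after transfer
(h.a.t.).

The pipeline is: frames → background subtraction and segmentation →
gap-free track linking → kinematics in 10-s bins → skeletonization and
head assignment → 24-angle posture vectors → eigenworms and a clustered
posture library with mirror merging → behavioral-state and turn
classification. A synthetic plate simulator with complete ground truth
(positions, midlines, state labels) backs every stage with an oracle, so
the whole chain is testable without a microscope.

# The synthetic plate simulator

`simConfig()` / `simulatePlate()` emulate the acquisition geometry of a
stereoscope-mounted camera: square frames (default 1024 px at
6.25 µm/px — a 6400 µm field) at 2 frames/s, bright background with
additive Gaussian noise, and worms rendered as dark thick curves
(transmitted illumination from below). Default contrast is 15× the noise
standard deviation; detection remains reliable down to roughly 5×.

Each worm is an inextensible midline of 26 points equally spaced along arc
length. Its tangent-angle profile is the sum of two sinusoidal spatial
modes (1.5 and 2.5 cycles per body) with a travelling phase — the
locomotion wave — so the simulated posture space is intrinsically
two-dimensional, matching the low-dimensional "eigenworm" structure the
analysis assumes. Centroids follow a state-dependent speed and
heading-persistence random walk driven by a three-state Markov chain:

| state | speed (mm/s) | heading persistence | bend scale |
|---|---|---|---|
| quiescent | 0.0005 | 0.90 | 0.4 |
| dispersal | 0.03 | 0.985 | 0.5 |
| dwelling | 0.008 | 0.88 | 1.0 |

No quantitative per-state speeds are available for this system beyond the
dispersal thresholds themselves, so the defaults were chosen once to
straddle those thresholds the way the real states do: dispersal is well
above 0.01 mm/s with ~7 °/s path curvature, dwelling is below 0.01 mm/s
with ~35 °/s (above the 15 °/s dispersal ceiling, below the 50 °/s
eigenworm cutoff), and quiescence is near-motionless. The reduced bend
scale in quiescent/dispersal states emulates the stiff, shallow-bend dauer
posture; dwelling uses the full bend amplitude. Body geometry defaults to
60 × 5 px (375 × 31 µm), a realistic dauer at this calibration.

Scripted turns overlay a large uniform-curvature bend (total ≈ 360°) for a
few seconds, producing the self-overlapping omega/U shapes that defeat
skeletonization; `renderTurnShape()` builds such shapes standalone and
labels them by the annotation rule used throughout: a shape is a *turn*
when head or tail touches the rest of the body, or when head and tail
point in the same direction (U-shape, end-tangent agreement within 45°).
An optional `stateSchedule` pins every worm to a given state from a given
time, which scripts behavioral switches with a known ground-truth time.

What the simulator does *not* emulate: bacterial lawn texture, lens
vignetting or illumination gradients, worm-worm collision avoidance, and
body-intensity structure (worms are uniform dark capsules). Passing tests
therefore demonstrate correctness of the algorithms under controlled
optics, not robustness to every artifact of real plates; the
background-subtraction and MAD-scaled thresholding are the components
designed to absorb the slowly varying intensity structure of real images.

# Segmentation

The background is the per-pixel temporal median over (optionally
stride-sampled) frames. This assumes each pixel is worm-free in more than
half of the sampled frames — true for moving worms and spans of minutes,
but a worm that is quiescent for most of a short clip bakes into the
background and is subsequently invisible; the downstream moving-only track
filter removes the same animals, so population kinematics are unaffected.

Each frame is segmented by smoothing the *signed* difference from the
background with a Gaussian (σ = 1 px), then thresholding its absolute
value at 5 times a robust noise scale (1.4826 × MAD of the smoothed
difference). Smoothing before taking the absolute value matters: the
absolute value of smoothed zero-mean noise concentrates near zero, whereas
smoothing |difference| concentrates it near its mean and invalidates the
MAD threshold. The sign-agnostic threshold makes dark-on-bright and
bright-on-dark objects equivalent, and a constant intensity offset applied
to frame and background cancels exactly. Components are hole-filled and
size-selected to `[0.5, 3] × length × width` — bounds derived from worm
geometry; the lower bound tolerates partial truncation at the field edge,
the upper bound excludes merged worm pairs, which are deliberately not
split (they fail skeleton validation anyway).

# Tracking and kinematics

Detections are linked frame-to-frame by greedy globally-nearest-neighbor
matching under a gate of one body length, ties broken by area difference.
There is no gap closing: a missed detection terminates the track, because
only gap-free tracks of ≥ 20 frames (10 s at 2 fps) enter analysis. A full
linear-assignment tracker would recover longer identities, but downstream
statistics are population averages over track segments, so identity
persistence beyond the gap-free segment has no value here.

Per 10-s bin, *speed* is the summed frame-to-frame centroid displacement
divided by elapsed time (mm/s), and *angular velocity* is the mean
absolute change in heading between successive displacement vectors times
the frame rate (°/s) — an operationalization of path curvature in the
stated units. Displacements under 0.5 px carry no usable heading and are
skipped; a bin with fewer than two usable headings reports 0 °/s with
`angvelDefined = FALSE`, so near-stationary animals are classified by
their speed rather than by centroid jitter. The first 30 min after
transfer are discarded (plate-handling artifacts), with the 0.5 h boundary
kept inclusive.

# Skeletons and posture

Masks are thinned to 1-px curves (Zhang–Suen), spurs up to 3 px are
pruned, and a skeleton is retained only if it is a single unbranched
8-connected path of arc length ≥ 26 px — self-overlapping turn shapes
produce loops or branches and are rejected, so the posture library never
contains self-occluded shapes. Endpoint and junction tests use the
crossing number (0→1 transitions around a pixel) rather than raw neighbor
counts, which overcount at staircase corners of 8-connected curves.

The head is the endpoint projecting furthest along the track's 3-frame
smoothed displacement (worms crawl head-first), accepted only when the
displacement is ≥ 1 px/frame and the projection gap exceeds 25% of body
length. Unresolved frames inherit orientation from the nearest oriented
frame of the same track by endpoint proximity; frames that remain
unresolved are discarded. Dorsal/ventral identity is not resolved at this
magnification — a worm and its mirror image are indistinguishable, which
is exactly why the posture library merges mirror pairs.

The posture vector is 24 signed intersegment angles: 26 points are fitted
at equal arc-length spacing along the midline, giving 25 chords and 24
inter-chord angles. Raw pixel paths carry quantization noise comparable to
the per-segment bend signal (chords are ~2.4 px), so the path is smoothed
with a cubic smoothing spline over arc length (df = 12), each point is
refined to the distance-transform-weighted center of the mask along the
local normal (sub-pixel medial correction), and the final angle vector is
lightly smoothed (moving average, window 3). These steps are linear in the
coordinates, so translation/rotation invariance and exact sign flip under
mirroring are preserved. On simulated scenes the recovered vectors
correlate with ground truth at median r ≈ 0.94 per frame; uniformly higher
per-frame fidelity is not attainable from binary masks of 5-px-wide
bodies, a resolution limit stated here deliberately. Continuous (already
sub-pixel) midlines bypass the smoothing; a perfect semicircular arc then
yields exactly 180°/25 = 7.2° per angle — the analytic value for equal
chords of a circle (the 24 angles measure the turning between the first
and last chord, not the full 180° tangent turning).

# Eigenworms and the posture library

Eigenworms are the eigenvectors of the covariance matrix of posture
vectors from *moving* worms: tracks of ≥ 5 s with speed > 0.01 mm/s and
angular velocity < 50 °/s. The library for one condition pools all
experimental repeats and clusters eligible vectors with k-means (k = 200).
We use `stats::kmeans` (Hartigan–Wong) with 10 random restarts under a
recorded seed; restarts serve the same robustness purpose as a k-means++
initialization while keeping the implementation in base R. Distances are
plain Euclidean on signed angles in radians — the coordinates already
share units.

Mirrored posture pairs (negated angle vectors) are then merged: candidate
pairs are ranked by ‖cᵢ − (−cⱼ)‖ and matched greedily, smallest distance
first, each centroid at most once, accepting a match only below the 75th
percentile of nearest-neighbor distances among centroids (a scale-free
gate). Greedy matching was chosen over strict mutual-nearest-neighbor
after measuring that k-means jitter breaks mutuality for ~20% of centroids
and caps the library reduction near 40%, whereas greedy matching reaches
the expected ≈ 50% on negation-symmetric data while remaining symmetric,
parameter-light and involution-consistent; a centroid whose best mirror
match is itself (a symmetric posture) stays self-paired.

Meta-postures re-cluster one representative per merged class — the
count-weighted mean of the pair after aligning the partner by negation,
sign-canonicalized so the summed angle is non-negative (otherwise the
representative's orientation would be a k-means artifact) — with k = 3,
pooling all conditions. Groups are relabeled in order of increasing mean
absolute curvature, so group 1 is always the stiff, dauer-like group.
Posture abundance over time uses 1-h h.a.t. bins by default: per-bin
relative class frequencies (rows sum to 1), z-scored per class across
bins; empty bins yield flagged `NA` rows. Meta-posture occurrence is also
reported normalized to the condition-wide mean occurrence of the group.

# Behavioral states and turns

A 10-s bin is *dispersal* iff speed ≥ 0.01 mm/s and angular velocity
< 15 °/s ("minimum speed" read inclusively, "below" strictly); quiescence
is reported descriptively as speed below the dispersal floor. Because
self-overlapping turns defeat skeletonization, turning is detected
directly from bitmasks: 17 shape descriptors (area, perimeter,
area/perimeter², axis lengths, eccentricity, solidity, extent,
hull-to-box ratio, skeleton endpoint count, skeleton length,
end-to-end/skeleton-length ratio, maximum convexity defect, box aspect,
Hu moments 1–2, mean distance transform) feed a seeded random forest
(500 trees, stratified 80/20 held-out split, score threshold 0.5). The
descriptor set is this package's own fixed definition, chosen to separate
elongated from self-contacting shapes. Per-frame turn flags are collapsed
to one event per 10-s window so a still worm flagged repeatedly counts
once.

# Numerical choices and degenerate inputs

Angles are wrapped to (−π, π]; zero-length chords raise errors rather than
NaNs. K-means ties and restarts are controlled by recorded seeds;
identical posture sets produce a zero covariance and an explicit warning
(empty basis) instead of a spurious decomposition. Empty frames, empty
detection lists, empty time bins and single-class training sets are all
defined outcomes (empty tables, flagged rows, errors naming the problem).
The temporal median uses a sort-based row median, exact for both odd and
even sample counts.

# Problem sizes in the test suite

The packaged tests run the full chain at desk scale, chosen to exercise
every code path in minutes: rendered scenes of 200–480 px with 2–5 worms
and 20–80 s of video; ground-truth-only simulations up to 40 min of
plate time with 10–30 worms for state-mixture and switch-recovery
checks; posture clouds of 10⁴ vectors (×2 after symmetrization) for the
k = 200 library; and 300–1000 rendered shapes for the turn classifier.
The same generators scale to full experiment sizes (1024 px, hours,
hundreds of worms) without code changes.

# Known limitations

Touching or overlapping worms are not split; their merged components are
size-filtered out, briefly interrupting tracks. Quiescent animals that
never move are absorbed into the background model and are measured only
once they move. Head assignment fails for tracks that never exceed
1 px/frame; such skeletons are discarded rather than guessed.
Dorsal/ventral turn direction is out of reach at this magnification by
design. Per-frame posture fidelity is bounded by mask resolution as
discussed above; library-level statistics average this noise away.
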