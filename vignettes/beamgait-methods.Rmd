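---
title: "Beam-walking posture analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-walking posture analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamgait)
```

## The problem

The balance beam test assesses vestibular and motor function in mice: an
animal traverses a 60 cm section of a narrow beam while two cameras record
it at 30 fps. Markerless pose estimation (DeepLabCut-style tracking)
produces per-frame 2D coordinates of 18 anatomical landmarks — 3 head
points (both ear tips and the nose tip), 4 torso points, 7 tail points and
the 4 feet. `beamgait` takes those tracking tables and turns them into
quantitative descriptions of gait: merged or 3D-reconstructed coordinates
in physical units, per-frame speed vectors, a *standard walk cycle* (SWC)
summarizing the animal's typical stride, drift-free synthetic walk
animations, and a per-cycle anomaly statistic, the *variance of
correlation* (VoC).

## Speed representation

All gait analysis operates on the stacked per-frame displacement vector

$$V(t) = X(t) - X(t - \Delta t),$$

where $X(t)$ collects every coordinate of every landmark in a fixed order
$(x_1, y_1[, z_1], x_2, \dots)$. For the 18-point skeleton $V(t)$ has
$|N| = 36$ components for 2D data and $54$ for 3D data. $V$ is kept in
units of *coordinate units per frame*: the template matching, weighting
and correlation semantics below all rely on this raw displacement form,
and conversion to cm/s (dividing by $\Delta t = 1/\mathrm{fps}$) is a
separate, explicit step. The backward difference drops frame 0, so a pose
with $F$ frames yields $F-1$ speed samples. Intervals where the animal is
not walking (stops, pre-box hesitation) are culled before cycle
extraction; culling keeps an index map so every per-cycle result can be
placed back on the video timeline.

## Standard walk cycle extraction

A walking bout is modelled as a sequence of contiguous cycles
$(t_i, \tau_i)$ with $t_{i+1} = t_i + \tau_i$: each cycle is the template
waveform time-rescaled to its own period. Extraction is seeded by a
one-cycle template (chosen by eye from the prominent foot-speed peaks, or
automatically by `suggest_template()` from the autocorrelation of the
summed squared foot x-speeds) and proceeds by template matching over an
integer period grid from half to double the template length.

Two scores appear here, and keeping them distinct matters:

* **Match metric (which period wins).** The normalized cross-correlation
  (cosine) between the rescaled template and the data window. It is
  scale-free in both amplitude and window length, so the arg-max lands on
  the true period; on strictly periodic input the recovery is exact. A
  projection coefficient cannot serve here: compressing the template
  shrinks its self-inner-product faster than the cross term, so the
  arg-max drifts off the true period even without noise (we observed 19/21
  around a true period of 20).
* **Cycle weight $C_{max,i}$ (how much a cycle counts).** The projection
  coefficient $\langle s, V_i\rangle / \langle s, s\rangle$ of the window
  on the rescaled template. It is dimensionless and carries the movement
  semantics used downstream: 0 for no movement, 1 for a template-like
  cycle, above 1 for the same movement at higher speed, negative for
  opposed movement.

Ties on the match metric resolve to the shortest period. Segmentation is
greedy left-to-right by default (each cycle closed before the next
starts — cheap and faithful to interactive use). A dynamic-programming
mode maximizes the *length-weighted* cosine sum over all contiguous
segmentations; the length weighting makes the global objective neutral to
how many cycles the domain is cut into (a plain cosine sum is maximized by
many short cycles). The DP mode is the right choice for short, noisy
recordings: under period jitter of ±2 frames and realistic tracking noise
the greedy pass recovers ~72% of periods to ±1 frame because one early
mistake shifts everything after it, while the DP pass recovers all of
them.

The SWC is then the $C_{max,i}$-weighted average of the cycles, each
linearly rescaled to the template length, with cumulative weight
$\sum_i C_{max,i}$. Cycles with non-positive weight would invert the
average and are dropped with a warning. The stored weight makes
*progressive refinement* a running weighted mean: a new video is segmented
with the current SWC as template and folded in as
$(w\,\mathrm{SWC} + \sum_i C_{max,i}\,\mathrm{cycle}_i)/(w + \sum_i C_{max,i})$,
so refinement order does not matter beyond floating-point tolerance, and
weights add. The SWC file format is plain text with 17-significant-digit
numbers, so save/load round-trips are bit-exact and refinement across
sessions is reproducible; a skeleton hash in the header prevents refining
with an incompatible configuration.

## Geometry: 90° merging and 45° reconstruction

**Opposed 90° cameras** give near-orthographic side views. Each view is
rotated into beam coordinates using the traced beam segment (x along the
beam, y up), scaled to cm from the known beam length, and the two views
are averaged point-wise. Because the cameras face each other, one image is
mirrored; `mirror = "x"` reflects the right view's beam axis before
averaging (appropriate when calibration lines are traced in image order).
A wrong mirror setting is detectable — matched foot x-speed components
become anti-correlated across views — and is warned about.

**45° stereo pairs** support full 3D reconstruction without a calibration
rig. The only calibration input is three pairs of parallel line segments
traced in both views: the beam edges, the outer goal-box edges, and the
goal-box entrance edges — three mutually orthogonal directions. The
pipeline is: fundamental matrix from the 12 traced endpoints by least
median of squares over minimal 8-point samples (exhaustive over the 495
subsets at the default input size; seeded random sampling otherwise);
canonical camera pair from the epipole; then the metric upgrade.

The upgrade deserves a note. Intersecting the reconstructed parallel pairs
fixes the plane at infinity, and mapping the three directions to the
coordinate axes enforces parallelism, orthogonality and the axis labels —
but those constraints *cannot* fix the relative scales along the three
axes, and on synthetic scenes that residual anisotropy reached tens of
percent on the short axes. `beamgait` therefore performs a proper
self-calibration: the three orthogonal vanishing points in each view
determine that camera's intrinsics through the image of the absolute conic
(zero skew and square pixels assumed — true of any modern smartphone
sensor), the essential matrix then gives the relative pose (cheirality
selects among the four decompositions), and a final rotation aligns the
three directions with beam-x, box-y and entrance-z. On noiseless synthetic
projections the full round trip is exact to machine precision.

Physical scaling sets one global scale from the traced beam's known length
and moves the origin to the beam start. If the beam is inclined by
$\theta$ while the box edges are truly vertical, forcing them orthogonal
shears the scene; the correction $x \leftarrow x + y\sin\theta$,
$y \leftarrow y\cos\theta$ undoes it exactly and is the identity at
$\theta = 0$. Triangulation is homogeneous DLT with per-point reprojection
residuals; when the two optical axes are within ~15° of collinear (the
opposed 90° rig), or the viewing rays cross at shallow angles,
intersections are unreliable and a warning says so — 3D reconstruction is
for the 45° configuration only.

## Synthetic walk generation

Replaying an averaged SWC drifts: averaging real cycles does not preserve
the closure condition that one period returns the posture to its starting
shape. Normalization enforces per-component period sums of $(V_x, 0, 0)$,
with $V_x$ the largest per-point net x-advance in the input (the beam
direction is the only admissible net motion). The enforcement is an
additive per-component constant — the smallest change meeting the
constraint, and one that leaves zero-speed stance phases at rest, which a
multiplicative rescale would not. Forward-Euler integration of the tiled,
normalized cycle from any initial posture then advances every point by
exactly $(V_x, 0, 0)$ per period, to machine precision. A 2D SWC can
animate a 3D posture; the lateral coordinate simply never moves.

## Event abstraction (VoC)

For each cycle and component, the normalized correlation
$\langle V_n, \mathrm{SWC}_n\rangle / \langle \mathrm{SWC}_n, \mathrm{SWC}_n\rangle$
(cycle rescaled to the SWC length) quantifies how that landmark moved
relative to the typical stride, with the 0/1/>1/negative semantics above.
The normalization is per component: a global normalization would not give
a row of ones for a cycle that matches the SWC. Components whose SWC
waveform is identically zero (e.g. stance-foot lateral speeds in clean
data) have no reference and score 0, flagged in an attribute.

The VoC is the *population* variance (second central moment, divisor =
group size) of those correlations within each body group, per cycle. It is
non-negative; it is 0 when a group deviates uniformly — including perfect
walking and complete stillness; and it grows when parts of a group move
inconsistently with the rest, which is the signature of slips, jumps and
hesitations. By default only x and y components enter, so 2D- and
3D-derived VoC values are directly comparable; a flag includes z.
`flag_events()` merely thresholds and merges consecutive hot cycles —
labelling an event a slip or a jump remains the analyst's call.

One honest limitation: a projection-based correlation is blind to
deviations *orthogonal* to the SWC waveform. A foot dipping below the beam
during stance, with its swing untouched, barely moves the statistic. Real
slips disrupt footfall timing as well, which the statistic sees clearly —
the simulator's slip model reflects this (dip plus a one-cycle timing
disruption). Saturation is equally inherent: once a foot's movement is
fully decorrelated from the SWC its correlation sits near zero, so VoC
response to ever-larger timing disruptions plateaus.

## The simulator: a stated world

The generator's defaults state one fixed world rather than tunable knobs:
18 points, 30 fps, a 60 cm beam, stride period 20 frames, stride length
5 cm (7.5 cm/s forward — an unhurried traverse), foot lift 1 cm, and the
2-3-3 support pattern: the diagonal pair FL+RR swings first, then FR, then
RL, so the body rests on 2, 3 and 3 feet within each stride;
`mirror_lateral` swaps left and right, as seen between individual animals.
Swing speed is a raised-cosine bump (smooth and compactly supported — the
functional form is not prescribed by any measurement, and any smooth
unimodal bump serves the recovery tests equally). Head, body and tail
points advance with small sinusoidal oscillations (positional amplitudes
0.25/0.1/0.35 cm, phases staggered per point). Tracking noise is Gaussian
on coordinates; "5% of swing amplitude" noise means sd = 0.075 cm against
the ~1.5 cm/frame peak swing speed. Period jitter rescales whole cycles to
integer lengths. Stereo rigs place pinhole cameras (f = 1000 px,
1280×720) either at 45° to the beam near its start or facing each other at
90°; pixel noise applies to tracked feature points, while calibration
lines — traced once on static structure — default to noise-free.

What a green test establishes: that the algorithms recover a gait whose
generating assumptions they share — strict (or jittered) periodicity,
additive Gaussian noise, an exactly known skeleton. What it does not:
robustness to occlusion, tracking identity swaps, lens distortion,
rolling-shutter effects, non-stationary gait, or any biomechanical
validity of the waveforms. The simulator is an oracle for the software,
not a model of mice.

## Numerical choices

* Cycle rescaling is linear interpolation on the normalized frame grid;
  rescaling to the same length is the identity, so noiseless recovery is
  exact.
* Score ties in segmentation go to the shortest period.
* Fundamental-matrix estimation Hartley-normalizes coordinates; LMS
  refits on inliers within 2.5 robust standard deviations of the best
  sample's median.
* The ill-conditioning warning fires at median ray-crossing sine < 0.1 or
  optical-axis collinearity within ~15°.
* SWC files store 17 significant digits; round trips are bit-exact.
* Skeleton identity is a 32-bit FNV-1a hash of the group structure.
* Interior tracking gaps up to `max_gap` (default 5) frames are linearly
  interpolated; longer or boundary gaps are errors, since they need manual
  curation, not silent guessing.

## Known limitations

* Sub-frame (continuous-time) cycle resolution is out of scope; periods
  are integers, and a ±half-frame phase error is inherent.
* The per-component correlation/VoC cannot separate "faster than usual"
  from "differently shaped" within one component; it is a screening
  statistic, not a classifier.
* Self-calibration assumes square pixels and zero skew; strong lens
  distortion violates the pinhole model and is not corrected.
* The HDF5 dialect of the tracking-table layout is not read in this
  build; export tables as CSV.
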