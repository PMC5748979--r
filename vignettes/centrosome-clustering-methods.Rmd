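---
title: "Quantifying biphasic centrosome clustering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biphasic centrosome clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrotrack)
```

## The problem

Cells carrying supernumerary centrosomes avoid lethal multipolar division by
gathering the extra centrosomes into two spindle poles ("clustering").
Live 3D imaging of centrin-GFP-labelled centrosomes shows that the distance
`d(t)` between a clustering pair evolves in two phases: a long stochastic
*search-and-capture* phase in which the centrosomes drift toward and away
from one another, and a short *motorized* phase of continuous directed
approach, driven by the minus-end-directed kinesin HSET, that begins once
the pair comes within 7-8 um and takes about 15 min to complete. Cortical
actomyosin contractility modulates the search phase: it restricts the
random excursions of the centrosomes (lower temporal SD of `d`), keeping
them within HSET's capture range. centrotrack implements the measurement
machinery behind these observations - spot localization, anchor-propagated
tracking, pair kinematics, tripolar-spindle geometry, and AFM elasticity
fitting - together with a synthetic-data generator so that every stage can
be validated against known ground truth.

## The synthetic generator: what it emulates

`simulate_pair()` models the separation `d(t)` directly:

* **Search-and-capture** is a discrete-time mean-reverting (AR(1) /
  Ornstein-Uhlenbeck-type) process, reflected at zero, with mean
  `mean_separation_search`, stationary SD `sd_search`, and reversion
  timescale `reversion_time`. The imaging literature characterizes this
  phase only by its confined to-and-fro movement and its SD, so a
  stationary confined process matching that SD is the minimal faithful
  model. With the 40 s frame interval and `reversion_time = 200` s the
  typical frame-to-frame separation change is about 1.1 um, consistent
  with a mean absolute centrosome speed of 0.02 um/s.
* **Motorized phase** begins at the first frame where `d` is at or below
  `onset_separation` (default 7.5 um, the middle of the reported 7-8 um
  band) *and* the pair is flagged `cluster = TRUE`. Proximity is necessary
  but not sufficient in the real system - pairs that come close do not
  always cluster - so sufficiency is encoded by the flag, not by distance.
  The descent to `final_separation` is linear over
  `ceiling(motorized_duration / frame_interval)` intervals
  (`motorized_duration = 900` s by default, the reported invariant 15 min).
* **Clustered plateau**: after completion `d` fluctuates about
  `final_separation` with SD 0.05 um. The plateau default of 1.8 um is a
  realistic separation for two centrosomes sharing one spindle pole and
  sits just under the 2 um completion threshold used downstream.
* **Condition contrast**: wild-type-like ensembles use `sd_search = 2` um,
  contractility-increased (E-cadherin-knockout-like) ensembles 1 um, the
  two reported regimes. Non-clustering pairs default to a baseline of
  11.5 um (the reported ~11-12 um); clustering pairs default to 8.5 um.
  The latter value is a design choice: no baseline is reported for
  successful pairs, but they must search within reach of the 7.5 um onset
  for clustering to occur on the timescale of one mitosis, and 8.5 um
  places the onset 0.5 SD below the search mean.
* **3D embedding**: positions are placed symmetrically about a fixed
  midpoint along a slowly precessing axis (small random rotation each
  frame), so the pairwise distance honours `d(t)` exactly while the
  individual trajectories still move in 3D. Only separation is analyzed
  downstream, so the embedding is otherwise free.
* **Anaphase onset** is recorded 2 frames after completion for clustering
  pairs (clustering completes just before anaphase in most observed
  events) and near the end of the movie for non-clustering pairs, where it
  serves as the population alignment event.

`render_stack()` turns truth positions into calibrated image stacks: each
centrosome is an anisotropic 3D Gaussian (lateral sigma 0.11 um, axial
0.35 um) on a constant background with optional Poisson (and Gaussian
read) noise. The default voxel grid follows the imaging protocol: 35
z-slices at 500 nm, frames every 40 s, 0.13 um xy pixels (the pixel size
after 2x2 binning is not documented for the original optics; 0.13 um is
our estimate for a 100x/1.45 NA objective and is configurable).

What the generator does **not** emulate: photobleaching, focus drift,
cell boundaries, other fluorescent structures, or interactions among more
than two centrosomes. Passing the recovery tests therefore demonstrates
the correctness of the measurement chain, not robustness to every
real-microscopy artifact.

`simulate_tripolar()` draws the smallest centroid-subtended inter-pole
angle from a truncated normal on (0, 120] degrees and constructs pole
coordinates realizing that angle exactly (angles theta, 180 - theta/2,
180 - theta/2 around the centroid), then applies a random rigid motion.
`simulate_force_curve()` solves the cantilever force balance
`k d = Sneddon(delta)` exactly, so emitted (z, deflection) samples follow
the conical Sneddon law with the requested modulus.

## Spot localization and tracking

Detection follows an anchor-propagation scheme. At *anchor frames* spots
are seeded either from replayed click coordinates (the original workflow
was human-in-the-loop) or automatically from local maxima of the
maximum-intensity z-projection above a robust threshold (median + 3 MAD).
We use a max projection for seeding; a mean projection differs only for
overlapping structures. Each xy seed receives the z-slice maximizing the
mean intensity of the 500 x 500 nm window around it (3 x 3 pixels at
0.13 um; nearest odd window, ties to the lower slice). Every other frame
is searched inside a spherical mask of radius `r = 2 * dt * v_avg`
(1.6 um at dt = 40 s, v_avg = 0.02 um/s) centred on the spots of the
adjacent frame one step closer to the nearest anchor; non-anchor frames
chain frame-by-frame toward their nearest anchor (ties toward the earlier
anchor). Candidate voxels must exceed a median + 3 MAD background
threshold - the original workflow relied on human vetting instead, so the
threshold is our addition. Detections are refined to subpixel centres by
least-squares fitting of an axis-aligned anisotropic 3D Gaussian plus
offset over a 7 x 7 x 5 voxel window, falling back to an
intensity-weighted centroid on degenerate windows.

Trajectories are assembled by *exact* globally optimal one-to-one
nearest-neighbour assignment between adjacent frames under the gate
radius (maximum matches first, then minimum total distance), rather than
greedy matching, whose result would depend on input order. Missed
detections are carried for up to 2 frames and filled by linear
interpolation when the track resumes; longer gaps terminate the track (at
40 s per frame and 0.02 um/s, extrapolating further is unreliable).
All indices in the package are 1-based (R convention) with voxel centres
at `(i - 0.5) * spacing`; coordinates are physical um throughout.

## Pair kinematics

**Completion** ("the time point at which separation stabilized") is made
operational as: the earliest frame from which `d` stays at or below
`d_clustered` (default 2 um) *and* every trailing window of 5 frames has
SD at most 0.3 um. Windows are evaluated *starting* at or after the
candidate frame: windows ending there would straddle the motorized
descent and could never pass, so the trailing-window form is the one
consistent with recovering the generator's truth.

**Phase segmentation** fits, over the window ending at completion, a
two-piece model: a constant plateau followed by a linear descent anchored
at the completion point. For each candidate changepoint the plateau level
is the mean of `d` up to and including the changepoint and the descent is
the least-squares line through `(t_completion, d(t_completion))`; the
changepoint sample contributes to both pieces, which makes the noiseless
minimizer unique, and ties break toward the earliest candidate. The
changepoint is the motorized onset; the fitted slope magnitude is the
motorized speed; `d` at the changepoint is the onset separation. A
non-negative fitted slope rejects the segmentation (e.g. pairs that never
descend). The exhaustive noiseless test verifies exact recovery against
a brute-force SSE scan for every changepoint position in series up to
length 60.

**MSD** uses the time-averaged lag estimator
`MSD(tau) = mean over pairs and start times of (d(t + tau) - d(t))^2`,
with both end points restricted to the phase window, so that the
search-phase MSD is not contaminated by the motorized descent. Whether
the original population MSD was lag-based or measured from a common
origin is not documented; both estimators are provided
(`estimator = "lag"` is the default, `"origin"` the alternative).

**Population alignment** (`align_population()`) aligns series at
completion or at anaphase onset and reports the cross-pair mean and SD of
`d` per aligned time; with the generator's stationary search process the
pooled cross-pair SD estimates `sd_search`, so a 2 um vs 1 um condition
contrast is recovered as a ratio near 2. The search-phase histogram
(`phase_histogram()`) pools `d` over the search phase of clustered pairs
and the pre-anaphase span of failed pairs and reports the median with a
bootstrap SEM (1,000 seeded resamples; the original figures print
"median ± SEM" without specifying the estimator).

## Tripolar geometry

The three poles subtend three angles at their **centroid**; they sum to
360 degrees and the smallest is at most 120 degrees. The original angle
measurement does not document its vertex (centroid, cell centre, ...);
the centroid is the only choice intrinsic to the pole coordinates and is
invariant under rigid motion and scaling, which the tests verify. With
3D pole coordinates the angles are measured in the poles' own plane,
where the centroid lies by construction. Rose histograms bin right-open
from 0 degrees (default width 10) with the last bin closed so 120 is
representable, and clustering efficiencies carry Wilson score intervals.

## AFM elasticity

Approach curves are postprocessed in four steps. (1) *Sensitivity*: on
glass the tip cannot indent, so deflection rises one-for-one with piezo
travel; the sensitivity is the inverse slope of the post-contact linear
region (robust `rlm` fit on the upper part of the rise). (2) *Contact
point*: the published analysis cites an external method whose details are
not reproduced; we scan every candidate contact point and minimize the
summed squared residuals of a flat pre-contact baseline plus a
Sneddon-form fit (`F = a delta^2`, `a >= 0`) beyond it, with parabolic
refinement of the residual profile, and declare "no contact" when the
two-piece model improves on a flat fit by less than 20 %. (3)
*Indentation*: `delta = (z - z0) - d`, `F = k d`, negative depths
dropped; repeat curves from one position are linearly resampled onto a
common depth grid and averaged. (4) *Modulus*: linear least squares of
`F` on `delta^2` restricted to depths of at most 800 nm - shallow depths
weight the cortex rather than the cytoplasm - via the conical Sneddon
relation `F = (2/pi) (E / (1 - nu^2)) tan(alpha) delta^2`. The Poisson
ratio defaults to 0.5 (incompressible cell, standard in AFM cell
mechanics) and the cone half-angle to 35 degrees, typical for the named
V-shaped tip class; neither value is documented in the original protocol,
and both are configurable. Only approach segments are analyzed.

## Numerical choices and degenerate inputs

* Gaussian fits bound sigmas and centres to the window and fall back to a
  flagged centroid on failure; noiseless fits reach residuals below
  1e-6 of the amplitude.
* Equal-intensity maxima inside a mask break ties toward the voxel
  nearest the prediction, then lowest z, y, x; `select_z` ties break
  toward the lower slice.
* The assignment step is exact branch-and-bound (spot counts per frame
  are tiny); it maximizes matches before minimizing summed distance, so a
  single far detection cannot steal a nearer track's match.
* `detect_completion` on series shorter than the stability window returns
  none with a warning; degenerate (flat) segmentations are rejected
  rather than forced.
* All simulation functions consume an explicit integer seed and are
  bit-reproducible; the workbench derives per-artifact seeds from the
  single config seed.

## Problem sizes

The bundled tests and the acceptance script run entirely on synthetic
data at deliberately modest sizes, chosen as the smallest ensembles whose
Monte-Carlo error is comfortably inside the tolerances being checked:
50 clustering pairs (60 frames each) for motorized-phase recovery, 40 +
40 non-clustering pairs for the SD contrast, a 15-frame 35-slice stack
for tracking fidelity, 200 random walks for the diffusive MSD limit, 200
noisy force curves for AFM bias, and 200 spindles for geometry.

## Known limitations

* The search-phase model is stationary; real pre-clustering dynamics may
  drift or be state-dependent, and anything the confined-SD summary does
  not capture is outside the generator.
* The tracker assumes near-point-source spots and no merging/splitting;
  it does not implement motion-model (Kalman) prediction.
* The two-piece segmentation assumes a single motorized episode; pairs
  with aborted approaches segment at the final descent only.
* AFM fits assume a conical indenter and depth-independent modulus;
  viscoelasticity and tilt corrections are out of scope.
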