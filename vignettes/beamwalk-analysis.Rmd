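---
title: "Beamwalk analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beamwalk analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamwalkr)
```

This vignette is the package's own account of the science it implements:
the measurement model behind each readout, the parameters that matter, the
numerical conventions at boundaries and degenerate inputs, what the
synthetic generator does and does not emulate, and the design choices that
were genuinely open.

## The measurement model

A beamwalk trial is a side-on video of a mouse crossing a narrow elevated
beam, reduced by markerless pose estimation to a per-frame table of
(x, y, likelihood) for a fixed label set: nose, left eye, four paws,
belly, back, three tail points, two beam-top landmarks and the two
markings that delimit the scored span. Image coordinates have their origin
at the top left with y growing downward; all vertical readouts are
therefore sign-flipped into a beam-relative convention.

**Beam geometry.** The beam top is modeled as the straight line through
the two beam-top landmarks. Because the landmarks are static objects
tracked with jitter, each is aggregated as the per-coordinate median over
its non-missing frames before the line is fitted; the median is robust to
heavy-tailed tracking error and makes the geometry independent of trial
length. Pixel scale comes from the only physical distance available along
the beam axis: the start/stop markings, a known `marking_span_cm` (39 cm)
apart, give `px_per_cm = |start_x - stop_x| / 39`, and the beam height in
pixels is `beam_height_cm` (2 cm) times that. Camera perspective is
ignored: the beam is filmed side-on from a fixed distance, so a single
global scale is an adequate first-order model. Lens distortion and
parallax along the beam are known, unmodeled error sources.

**Beam-relative position.** A point at image position (x, y) is reported
as `(y_beam(x) - y) / beam_height_px * 100`, i.e. percent of beam height
above the beam top: 0 % on the beam top, +100 % one beam height above,
negative below. The quantity is invariant under translation of the whole
scene and under uniform rescaling, because the calibration landmarks
rescale with the points — both properties are tested.

**Slips.** A slip is a transient excursion of a paw below the beam top.
Excursion depth is `-position` (in percent, 0 for points on or above the
beam). Extremum depth classifies the event: hindpaw 20–50 % minor,
> 50 % major; forepaw 10–30 % minor, > 30 % major. The boundary exactly at
the major threshold counts as minor — "between 20 and 50" is read as
inclusive and "deeper than 50" as strict, which makes the partition
exhaustive and disjoint; minor and major tallies never overlap.

**Posture.** The tail-base angle is the angle at the tail base between
the ray to the nose and the ray to the tail tip, reported in [0°, 360°):
the unsigned vector angle when the tip is at or above the tail-base
height, and 360° minus it when the tip hangs below. The tail center
substitutes for an occluded tail tip (`used_fallback` records this), which
is why interpolated points deliberately inherit the *smaller* flanking
likelihood during conditioning — weakly tracked tail tips keep triggering
the fallback. Body area is the shoelace area of the quadrilateral through
nose → back → tail base → belly; this anatomical perimeter order (dorsal
points out, ventral point back) avoids self-intersection, and the area is
invariant under rigid motion and cyclic vertex rotation.

## Pipeline stages and their parameters

**Conditioning** (`condition_tracks()`), per label, in fixed order:

1. *Likelihood gate*: points with likelihood < `p_cutoff` (default 0.2,
   unitless in [0, 1]) are marked missing.
2. *Velocity gate*: a point whose Euclidean displacement from the previous
   surviving point exceeds `max_jump_px` (default 30 px/frame at 50 fps)
   times the number of frames elapsed is marked missing. The per-frame
   scaling matters: after a long occlusion the animal has legitimately
   moved, and a fixed pixel threshold would discard everything after the
   gap, while a velocity threshold only rejects physically implausible
   speed. 30 px/frame at 20 px/cm and 50 fps corresponds to 75 cm/s,
   several times normal crossing speed.
3. *Gap closing*: missing runs of at most `max_gap_frames` (default 10,
   i.e. 0.2 s) flanked by valid points are filled by per-coordinate linear
   interpolation. Interpolation keeps event detection contiguous across
   single-frame dropouts; anything longer stays missing and, downstream,
   terminates slip runs rather than bridging them.

Conditioning is idempotent (re-running changes nothing — tested on random
tables) and never touches a point that passed both gates outside an
interpolated gap. Whether the original analysis dropped, interpolated or
carried sub-cutoff points forward is not documented anywhere we know of;
mark-and-interpolate with config-exposed defaults is this package's
explicit policy.

**Segmentation.** Trial windows are gated *per analyzed label*: the paw's
own x position decides which frames count for paw analyses. A frame is
stationary when belly, back and tail base each moved at most
`stationary_threshold_px` (1.5 px) since the previous frame — Euclidean
displacement, with missing reference points conservatively making the
frame non-stationary, and the first frame never stationary. Stationary
frames are excluded from every averaged measure and from event detection,
so a mouse pausing mid-beam neither dilutes position distributions nor
generates spurious long "slips". Trial length is the count of valid
(in-span, non-stationary, non-missing) frames over the frame rate; whole
frames are used, with no entry/exit interpolation. Travel direction is
the sign of the median per-frame x displacement of the back label within
the span; all reported metrics are direction-agnostic.

**Event detection** (`detect_slip_events()`). The depth trace of one paw
on its trial segment (with stationary/missing frames absent, so frame
indices may have holes) is turned into discrete events by:

1. *Runs*: maximal stretches of entries at or beyond the minor threshold.
   Interruptions shorter than `min_separation_frames` (3) above-threshold
   entries do not break a run; an absent-frame gap longer than
   `max_gap_frames` always does (events may not span unobserved time). A
   run qualifies only if it contains at least `min_duration_frames` (2)
   frame-consecutive below-threshold entries — single-frame spikes are
   noise, not slips.
2. *Valleys*: local depth maxima within a ±`floor(valley_window/2)`-frame
   window (`valley_window` = 5), ties resolved to the earliest frame of a
   plateau; valleys closer together than `valley_window` frames are merged
   keeping the deeper one. The merge step is the "spacing" criterion: with
   per-frame noise, a single physical dip otherwise sprouts several
   window-maxima near its extremum.
3. *Splitting*: adjacent surviving valleys delimit two events when the paw
   rebounds between them by at least `split_prominence_pct` (10 percentage
   points of beam height): the lower of the two valley depths minus the
   intervening minimum. The split is placed at the first intervening
   minimum.

Each event is classified by its extremum depth; a major event is *not*
additionally counted as minor. All four event parameters are config-
exposed; their defaults are declared here, not recovered from any
original implementation. The same frozen definition is implemented twice:
the production path and `slip_events_bruteforce()`, a deliberately naive
loop-based re-derivation sharing no code with it. The test suite and the
acceptance script require full agreement between the two on a thousand
adversarial random traces (random walks across the thresholds, injected
square-pulse dips, absent-frame gaps).

**Statistics.** Per-mouse means over non-empty trials feed two-tailed
Mann–Whitney U tests. The statistic counts pairs with `a < b` plus half
the ties, reporting `min(U, nA*nB - U)`; the p-value is exact — full
enumeration of rank assignments via a rank-sum recursion — when
`nA + nB <= 16` with no ties, and the tie- and continuity-corrected normal
approximation otherwise. Typical beamwalk designs (two groups of ~8 mice)
land in the exact regime; which variant the field's ad-hoc scripts use is
rarely stated, so the switch is explicit here. Holm's step-down
adjustment is applied within the family of pairwise comparisons for one
measure at one age (three pairs for three groups), matching per-panel
correction practice; a global family across measures would answer a
different question. Density summaries use a Gaussian kernel with
Silverman's bandwidth on a grid spanning the data ± 3 bandwidths,
renormalized to trapezoid integral 1 on that grid (the Gaussian tails
beyond ± 3 bandwidths carry ≈ 0.3 % of mass, which would otherwise break
the integral invariant). Frames are pooled across mice within a group for
densities — distributions describe frames, boxplots describe mice; a
per-mouse-weighted density is a one-line variant via per-mouse calls.

## Numerical conventions at the edges

- Tail angle with the tip exactly at base height takes the "above" branch
  (the unsigned angle), so 0° and 180° behave as colinear boundary cases;
  a zero-length tail or nose vector yields a missing angle, never NaN
  arithmetic.
- A depth exactly at the minor threshold is in the run; exactly at the
  major threshold is minor.
- Valley ties go to the earliest frame; equal-depth valley pairs closer
  than the window keep the earlier; extremum ties report the first frame.
- Missing points propagate as missing (`NA`) through every downstream
  computation; no coordinate of a missing point is ever used.
- Degenerate geometry (coincident beam landmarks, coincident markings,
  fully missing landmark labels) raises an error naming the label rather
  than producing a nonsense calibration.

## What the synthetic generator emulates — and what it does not

`generate_trial()` renders 50 fps, 1920×1080 coordinate streams: body
labels ride the beam line at configured percent-of-beam-height offsets
with a sinusoidal gait bob; paws oscillate at the stride frequency
(default 4 Hz) with a 12 % lift — deliberately below the shallowest slip
threshold — and dip below the beam exactly as prescribed (smooth cosine
dips by default, so valley detection sees realistic shapes; square pulses
for worst-case oracle tests). Pauses freeze the whole animal at its
bout-entry coordinates, satisfying the 1.5 px stationarity rule exactly
from the second bout frame; dropouts push likelihoods below the 0.2
cutoff; Gaussian pixel noise (default 2 px at cohort level, i.e. 5 % of a
40 px beam) corrupts all animal labels; beam landmarks and markings get
one third of that jitter. `generate_cohort()` adds the minimal hierarchy
the group statistics assume: Gaussian between-mouse variation on body
offsets (SD 5 percentage points) and Poisson slip counts per trial, with
ataxic mice crossing at half the control speed — which is both
phenotypically realistic and what makes a high slip rate physically fit
into one crossing. Slip windows are placed uniformly at random inside the
paw's in-span time with a 0.3 s minimum gap; windows that cannot fit are
dropped, and the ground truth records what was actually placed.

What passing tests on this generator shows: the pipeline recovers known
events, offsets and stationary bouts through the full read → condition →
geometry → segment → detect chain under realistic noise, and the group
statistics have their nominal operating characteristics under the assumed
hierarchy. What it does not show: robustness to real tracking pathologies
(label swaps between paws, systematic occlusion during slips, perspective
drift, fur-dependent likelihood miscalibration), to gait irregularity
beyond a fixed stride frequency, or to beams filmed off-axis. Real
deployments should validate against a manually scored subset via
`validate_against_manual()`, which reports agreement at the standard ±1
slip tolerance alongside a Mann–Whitney check for systematic bias between
rater and pipeline.

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses: 1000
random depth traces for detector-versus-oracle equivalence; a 2-group ×
8-mice × 3-trial cohort at 2 px noise (and again at zero noise) for
ground-truth recovery; every tie-free rank pattern up to total n = 10 plus
1000 random p-vectors for the statistics; 1000 random triples for the
angle mirror property; and 100 replicates each for type-I and sensitivity
of the group comparison. These sizes give stable pass/fail behavior at
interactive runtimes and are the package's declared validation conditions.

## Known limitations

- Single-animal, single-crossing videos only; multi-crossing splitting
  and fall detection are out of scope (falls end trials and are scored by
  the experimenter).
- Right-paw analyses are not produced (tracked only for completeness in
  the standard label set).
- No lens or perspective correction; calibration assumes the marking span
  is parallel to the image plane.
- The event-parameter defaults (duration 2, separation 3, window 5,
  prominence 10) are declared conventions; different camera geometries or
  frame rates may need retuning through the config.
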