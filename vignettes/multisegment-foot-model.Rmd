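---
title: "The four-segment kinetic foot model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The four-segment kinetic foot model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footmodel)
```

## The model

`footmodel` tracks four foot segments — hindfoot (calcaneus), midfoot
(navicular, cuboid, cuneiforms), forefoot (metatarsals) and hallux — plus
the shank as the ankle's proximal reference, from eleven skin markers per
foot (malleoli MM/LM, top and bottom calcaneus TC/BC, talar head TH,
navicular NV, cuboid CB, 1st and 5th metatarsal heads, a marker between the
2nd/3rd metatarsal heads, and the hallux nail bed) and two knee markers.
Three virtual markers are inter-marker midpoints: the ankle joint centre
(MM–LM), `V_MidNC` (NV–CB) and `V_15MTH` (1st–5th metatarsal heads). The
inter-malleolar midpoint is used as the ankle joint centre because the
marker set offers no better estimate; functional joint-centre methods are
out of scope.

Each segment frame is built from three markers: z from the Origin to the
Long-Axis marker (the segment length is their distance), x as the
right-handed normal of the plane through all three markers, y completing
the triad, followed by fixed intrinsic offset rotations (applied about the
segment's own axes in the order x, y, z; only z-offsets of 0/±90/180° are
needed by the shipped definitions). The definition table is a packaged YAML
(`inst/extdata/segment_definitions.yaml`) and can be overridden.

### Handedness and clinical signs

A frame with x pointing to the subject's *left*, y up and z anterior —
the way foot-segment axes are often described — is left-handed and cannot
come out of a right-handed construction. Our frames keep z anterior and y
up, which forces x to point to the subject's *right* on both sides
(lateral for the right foot, medial for the left). Consequently a positive
raw rotation about x is plantarflexion on either side, while positive raw
rotations about z and y tip the sole and swing the toes toward the
subject's right. The clinical convention (dorsiflexion, inversion,
internal rotation / hallux abduction positive) is obtained with the
component signs (−1, −1, −1) on the right and (−1, +1, +1) on the left;
an exact left/right mirror-symmetry test in the suite pins this down.
Moments can be reported in the `"plantar"` convention
(plantarflexion/inversion/internal-rotation moments positive, the common
choice for foot kinetics) or `"dorsi"` (sagittal sign matching the angle
convention).

### Angles, MLA, events, normalization

Intersegmental motion is the distal segment relative to the proximal one,
decomposed by the x–z–y Cardan sequence `R = Rx(α)·Rz(β)·Ry(γ)`; a warning
is raised within 0.1° of the gimbal singularity at β = ±90°. The MLA
height/length ratio uses the 1MTH–BC distance as length and the
perpendicular distance of NV from that line as height; it is dimensionless
and invariant to rigid motion and uniform scale.

Markers are low-pass filtered with a zero-phase Butterworth (order 2 per
pass, forward–backward, i.e. 4th-order effective) at 6 Hz by default;
zero-phase filtering avoids shifting gait events. Because
`signal::filtfilt()` assumes zero initial state, the series is padded by
odd reflection (six time constants) and de-meaned before filtering —
without this, marker coordinates (hundreds of mm) acquire large edge
transients. Gaps up to 5 frames are linearly interpolated before
filtering; longer gaps in required markers are an error rather than a
guess.

Heel strike is the first frame where the vertical force reaches the
contact threshold (default 20 N, a common laboratory choice); toe off is
the first subsequent frame below threshold minus a 5 N hysteresis. With a
single plate there is usually no second ipsilateral heel strike, so the
cycle end is extrapolated as `heel_strike + stance/0.60`, the average
stance fraction of healthy walking; a known cycle length can be supplied
instead. Curves are normalized to 101 points (0–100% of the cycle) by
linear interpolation. No static-trial zeroing is applied: outputs are raw
relative orientations, including each joint's neutral offset (an optional
calibration subtraction would be a thin wrapper, but the default reports
what the frames measure).

## Kinetics

The whole-foot mass defaults to 1.37% of body mass and the per-axis radii
of gyration to (0.257, 0.245, 0.124) of segment length — standard adjusted
cadaver-table values; the toe volume fraction defaults to τ = 0.08.
Segment masses follow the volume apportioning rule: hindfoot half of the
non-toe foot mass, midfoot and forefoot a quarter each, hallux τ of the
whole foot, under homogeneous density; centres of mass sit halfway along
each segment's long axis and the inertia tensor is diagonal in the segment
frame, `I_k = m (r_k L)²`. All of these are editable parameters, not
measurements.

Linear accelerations come from central differences of the centre-of-mass
path, angular velocity from the skew part of `Ṙ Rᵀ`, angular acceleration
from differencing ω; end frames use one-sided differences. For each joint
the distal free body contains every segment beyond it; the full
single-plate ground reaction (force at the CoP plus the free vertical
moment) is applied to every joint's free body, and inertial/gravitational
terms of the distal segments are retained. Joint centres are the
inter-malleolar point for the ankle *and* the Chopart joint (the midfoot's
frame origin is the ankle joint centre in the definition table), `V_MidNC`
for the Lisfranc joint, and the 1st metatarsal head for the 1st MTP.
Moments are resolved in the proximal segment's frame and normalized by
body mass; power is `M · (ω_child − ω_parent) / mass` in the lab frame.

Attributing the whole ground reaction to each free body overstates distal
joint loads early in stance, so the CPcross convention masks each joint's
kinetics until the CoP has crossed anterior to its centre, "anterior"
being the stance-phase progression direction estimated from the heel
marker's displacement. Masking sets flags only — values are never altered
— and the crossing indices are non-decreasing from ankle to 1st MTP for a
monotone heel-to-toe CoP. On the synthetic healthy trial the crossings
fall at roughly 14, 14, 25 and 43% of the cycle (the ankle/Chopart tie is
forced by their shared centre).

A deliberately plain frame-by-frame re-implementation of the free-body
solution (`newton_euler_reference()`) ships in the package; the test suite
requires the vectorized production path to agree with it to 1e-6 N·m on
randomized synthetic trials, and to reproduce closed-form statics
(massless segments under an anterior CoP; pure gravitational loading)
to 1e-9.

## Reliability statistics

The coefficient of multiple correlation uses Kadaba's within-day
formulation — the variance of trials about the time-point means, relative
to the variance about the grand mean:

$$R = \sqrt{1 - \frac{\sum_{j,t}(Y_{jt}-\bar Y_t)^2 / (T(M-1))}
                    {\sum_{j,t}(Y_{jt}-\bar Y)^2 / (MT-1)}}$$

chosen as the de-facto standard for gait waveform repeatability. A zero
denominator (identical flat curves) or negative radicand is reported as
*undefined* rather than clamped, so degenerate ensembles stay visible.
Labels follow the conventional bands, with the boundary R = 0.7 assigned
to "strong". The same formula is applied to test–retest (between-session)
ensembles; no between-day variance decomposition is attempted.

## The synthetic gait generator

The generator is a forward model, not a simulation: a shank trajectory
(forward progression with a slow-in-stance profile, small vertical bounce
and sway, ±16° sagittal tilt) carries a chain of rigid segments, each
rotated relative to its parent by prescribed x–z–y waveforms equal to the
neutral-posture angles plus periodic-spline excursions. Excursion
templates are rescaled so their extrema match healthy ranges of motion
(hindfoot sagittal 26.3°, midfoot 6.5°, forefoot 14.2°, hallux sagittal
37.3°, hallux abduction 11.6°), and the arch templates are phased so the
MLA ratio falls through stance to a minimum in terminal stance (around
35–40% of the cycle) before rebounding after toe off, within the healthy
0.10–0.20 band. Markers ride rigidly on their segments; optional
isotropic white noise (SD in mm *per coordinate*) is added afterwards,
under a seed that is restored to the caller.

The vertical GRF is a half-sine loading envelope modulated by a second
harmonic — peaks near 30% and 70% of stance, a midstance valley, and a
steep, physiological linear rise at contact — scaled so its stance-phase
mean equals body weight (making the stance impulse equal body weight times
stance duration; real single-foot traces average nearer 0.85 of body
weight, the price of that normalization being peaks around 1.5 BW).
Anterior-posterior and lateral shears and a small free vertical moment are
added as sinusoids. The CoP interpolates from under the heel marker to
under the hallux marker across stance, riding on the (moving) foot. The
plate stream is generated at 1200 Hz and the markers at 60 Hz, the typical
laboratory rates.

Two properties tie the geometry to the skeleton definitions so that the
kinematic pipeline recovers the prescribed waveforms *exactly* (to ~1e-13°
noise-free): the NV–CB pair straddles `V_MidNC` along the midfoot frame's
(tilted) medio-lateral axis, and the 2nd/3rd metatarsal marker lies along
the forefoot frame's medio-lateral axis from the 1st metatarsal head.
These placements mirror real anatomy (navicular above cuboid) while
guaranteeing that the plane-marker directions are exactly the parent
frames' x-axes.

### What the generator does and does not emulate

It emulates rigid-segment walking with laboratory sampling rates, additive
white marker noise, and a plausible single-plate load. It does **not**
emulate soft-tissue artifact (correlated, low-frequency), marker
occlusion/gap patterns, force-plate noise or drift, multi-plate targeting,
or forward-dynamic consistency between the prescribed kinematics and the
GRF (the two are prescribed independently; ground-truth kinetics are
defined by the same free-body equations the production code solves,
implemented separately). Passing recovery tests therefore demonstrates
correctness of the geometry, angle, event and dynamics code — not
robustness to the systematic artifacts of real skin-mounted markers.

### The slaved twist of forefoot and hallux

The skeleton definitions take the forefoot's plane marker (NV) and the
hallux's plane marker (2nd/3rd metatarsal) from the *parent* segment. The
constructed frame of those segments therefore inherits its long-axis twist
from the parent: a true independent frontal-plane rotation of the forefoot
about its own long axis moves the individual metatarsal markers but not
the constructed frame. This is a property of the model itself, not of this
implementation — it is consistent with the small forefoot
inversion/eversion ranges such models report, which arise largely from
out-of-plane coupling. The generator's default waveforms accordingly hold
the Lisfranc and 1st-MTP frontal-plane prescriptions constant; prescribed
(constant) twist is then recovered exactly.

## Numerical choices and error budget

* Frame orthonormality is maintained to ~1e-12; collinear marker triples
  (cross-product norm below 1e-9 of the marker scale) raise an error.
* Cardan extraction clamps the sine of β to [−1, 1] and warns within 0.1°
  of ±90°; composition/extraction round-trips hold to 1e-9° for |β| < 75°.
* Resampling 1200 → 60 Hz uses a zero-phase anti-alias filter at 80% of
  the target Nyquist followed by linear interpolation at frame times; CoP
  is interpolated only inside contact, pinned to the nearest contact
  sample at the boundaries (the anti-alias filter spreads force onset by a
  fraction of a frame). Upsampling is refused.
* With 2 mm-per-coordinate white marker noise and the 6 Hz filter, the
  pooled RMS waveform-recovery error of the full pipeline is ~1.7° (seed
  dependent, ~1.5–1.9°). The budget is dominated by the frontal-plane
  (long-axis twist) angles: their plane-marker levers are anatomically
  only ~30–37 mm, and 2 mm noise filtered at 6 Hz leaves ~0.8 mm, i.e.
  1.5–2.5° of twist noise per frame pair, against ~0.5–1.5° for sagittal
  angles with their longer levers. This ordering matches the published
  experience with such marker sets, where frontal-plane angles show the
  lowest repeatability. Sub-degree pooled errors require sub-millimetre
  effective noise.
* Problem sizes in the validation suite are chosen for speed at full
  coverage: single synthetic trials of ~2.4 s (≈150 marker frames, 2900
  plate samples), 20 randomized trials for the dynamics oracle, 1000
  random rotations for the Cardan round-trip, 10 × 3 curves for the CMC
  study; the whole suite runs in well under a minute.

## Known limitations

* Only TRC and long-format CSV marker files are read; binary C3D is not
  parsed (no suitable R reader; convert with any mocap toolchain).
* Single-plate kinetics: when more than one segment is loaded (midstance),
  attributing the whole GRF to each free body is an approximation; CPcross
  masks but does not partition. Two-plate and pedobarographic partitioning
  are out of scope.
* The shank frame uses knee/ankle centres from marker midpoints; no hip or
  full lower-body model is included.
* The hindfoot long axis (heel to ankle centre) is inclined ~38° above the
  horizontal, so its "anterior" z-axis is anterior-superior; this is
  inherent to the marker definitions, and neutral offsets are consequently
  large for the ankle. ROMs and excursions are unaffected.
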