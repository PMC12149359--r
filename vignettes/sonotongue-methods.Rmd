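---
title: "Quantifying artificial tongue deformation from B-mode ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying artificial tongue deformation from B-mode ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

During oral processing, a food gel is crushed and sheared between the
tongue and the hard palate. On a tongue-palate bench, a PVA-cryogel
"artificial tongue" carries a food gel that an aluminium palate
compresses and shears while an ultrasound array under the tongue records
B-mode images at 60 Hz and a multi-axis sensor records normal and
tangential forces at 25 kHz. `sonotongue` implements the image-analysis
side of such experiments: tracking the bright dorsal-surface echo with
an open active contour, converting its depth to pulse-echo time of
flight (ToF), and measuring bulk tissue velocities by particle image
velocimetry (PIV) — plus a synthetic speckle phantom with analytic
ground truth, because the bench recordings themselves are not
distributable and algorithmic claims need a world where the truth is
known.

## The imposed motion protocol

The bench applies one uniaxial compression followed by four horizontal
shear strokes, every motion at 2.5 mm/s and followed by a 1.5 s rest:

* compression of 15 mm (75% engineering strain on a 20 mm sample),
  hence 6 s of motion, ending at t = 6 s;
* strokes of 5, 10, 10, 10 mm whose directions alternate
  (+5, −10, +10, −10 mm) so the motion oscillates between +5 and −5 mm
  around the start; the shear phase spans 7.5–26 s with stroke
  boundaries at 9.5, 15, 20.5 and 26 s.

`build_schedule()` produces these segments exactly; phase lookups treat
segments as right-open intervals so a boundary instant belongs to the
later segment. The schedule ends when the final stroke ends (26 s);
`render_sequence(tail_s =)` appends quiescent frames when the analysis
needs to observe relaxation after the last stroke. Note that the net
shear displacement is −5 mm: with amplitudes 5, 10, 10, 10 no sign
pattern can return exactly to the start, and the implementation makes
that explicit rather than pretending closure.

## The phantom: a stated world, not a fit

`render_sequence()` draws a scatterer field (bulk Poisson field with
Rayleigh amplitudes at 3 scatterers/mm², a dense line of strong
reflectors on the dorsal surface at 6x the mean bulk amplitude, weak gel
speckle at 10% above it), displaces it with an analytic deformation
model, splats a separable Gaussian point-spread function
(sigma 1.2 px axial x 2.0 px lateral at 18.3 px/mm), log-compresses and
quantizes to 8 bits. A 1 mm dark margin at the lateral frame edges
mimics the aperture falloff seen in bench images; without it the bright
surface line would touch the image border and the chain's clear-border
step would (correctly, per its definition) delete it. The additive
electronic noise is time-varying, with each frame's realization derived
deterministically from the master seed and the frame's kinematic state:
identical states (every frame of a zero-amplitude protocol) therefore
render bitwise-identical frames, while moving sequences get temporally
decorrelated noise — a noise field frozen across frames would act as a
static overlay pattern and measurably bias PIV toward zero
displacement. An RF mode (6 MHz carrier, analytic-signal envelope)
exists for realism checks but envelope rendering is the default since
contour and PIV behaviour depend on speckle statistics, not the
carrier.

The deformation model is kinematic, not constitutive:

* **Compression.** A fraction `compression_share` (default 0.35, the
  softer member of a two-springs-in-series pair absorbing more of the
  15 mm) of the stage displacement compresses the tongue, decaying as a
  lateral Gaussian of width `contact_width` (8 mm) and linearly with
  height above the fixed base. After the compression ends the imprint
  recovers exponentially (`vertical_recovery_tau` = 10 s toward a 15%
  residual), emulating gel rearrangement; this is what makes the ToF
  fluctuation maps peak at t = 6 s and residual deformation decay over
  the shear cycles.
* **Stick-slip shear.** The dorsal surface loads elastically against
  the palate until its displacement demand exceeds
  `static_friction_threshold` (1.2 mm), then slips: the retained
  displacement drops exponentially (time constant `slip_tau` = 0.4 s)
  to `slip_retention` (0.6) of the threshold, and relaxes after the
  stroke stops (`rest_tau` = 0.25 s) toward `rest_retention` (0.5) of
  the stroke-end value, leaving a residual that the next stroke must
  first unload. During stick the displacement follows a
  quadratic-in-time profile reaching the threshold exactly at
  (distance-to-slip)/(stage speed): the surface velocity therefore ramps
  linearly and peaks exactly at slip onset, reproducing the triangular
  onset peaks of bench velocity traces while keeping the static-phase
  duration equal to the textbook closed form. A constant-velocity stick
  (the naive model) has no unique velocity maximum, which would make
  "onset peak time" undefined under measurement noise.

`stick_slip_profile()` exposes the per-stroke closed form (stick
duration, slip time, residuals); it is the oracle against which the
detection pipeline is validated, never a component of that pipeline.

What the phantom does **not** emulate: attenuation and time-gain
compensation, beam-width variation with depth, reverberation and
shadowing, gel fracture geometry, out-of-plane motion, or any real PVA
constitutive behaviour. A green test therefore establishes that the
algorithms recover imposed kinematics from realistic speckle — not that
the bench physics is as modelled.

## Surface conditioning chain

`preprocess_frame()` composes the published chain: Gaussian smoothing
with a 2 px (depth) x 10 px (lateral) support (sigmas extent/4, i.e.
0.5 and 2.5 px, reflect padding), a 5x5 median, Sobel gradient magnitude
normalized by its maximum with responses under 0.6 zeroed and survivors
carried on the 0–255 scale, retention of 150–225, dilation by a
vertical line, a 45-degree line and a radius-1 disk, removal of
8-connected components touching the border, and erosion by a radius-1
diamond. Choices made where the chain description is ambiguous:

* the 2x10 kernel smooths along the surface and preserves depth
  localization; the transposed orientation is selectable
  (`transpose_kernel`);
* the edge operator is Sobel with max-normalization (none is named);
* "line, size 1" elements are read as 3-pixel lines: their vertical and
  diagonal growth bridges the 1–2 px gap that the 150–225 band leaves
  at the gradient apex. With literal single-pixel (identity) lines the
  band misses the true interface row at ~8–10% of columns under
  compression, violating the 95% recall the chain is supposed to
  deliver;
* on a structureless noise frame the thresholded mask stays below 1%
  foreground; the subsequent dilations grow that to a few percent, so
  "near-empty" is asserted at both points.

On phantom frames the refined band is ~11 px wide and covers the true
surface row at >99% of supported columns at 0, 37.5 and 75%
compression.

## Open active contour

The contour is an open snake with 100 nodes at fixed lateral stations
spanning the frame width; only depth evolves (the dorsal surface is
single-valued in x). The energy is
`alpha * E_int + lambda * E_ext` with `E_int` the squared first
differences plus `band_penalty` times squared second differences of node
depth — normalized by the station spacing, so the published weights
(alpha 0.80, lambda 0.95, band penalty 2) measure slope and curvature
rather than raw pixel offsets and remain meaningful at any spacing — and
`E_ext` minus the normalized external strength at the nodes.

The external attractor defaults to the *smoothed image intensity*
("ridge" mode): the dorsal surface in B-mode is a bright line, and a
gradient-magnitude attractor locks onto a flank ~2–3 px off the crest
(measured: 2.7 px RMSE vs 0.07 px for ridge mode on the same phantom).
Gradient mode remains available for step-edge targets. Optimization is
greedy coordinate descent over offsets of ±delta (2 px) on the
coarse-smoothed map (sigma 5), then the fine map (sigma 2), then a 1 px
pass and a parabolic sub-pixel fit; each sweep first tries a collective
shift of the whole contour, which changes no internal term and lets a
uniformly offset contour ride to the interface without paying the
tension cost that blocks single-node moves. Energy is non-increasing by
construction within every stage, and tracking warm-starts each frame
from the previous solution (re-initializing from the band, with a
warning, if the mean inter-frame jump exceeds 30 px).

Depth conversions: mm = px x 10/183 and two-way ToF = 2 d / c with
c = 1540 m/s. Images put the transducer at the bottom edge (the array
sits under the tongue), so the pixel-space "depth" (row index) increases
downward while the acoustic range of row r is (nrow + 0.5 − r) px; the
`px`/`mm`/`tof` views of a contour table use the acoustic range, making
the three views mutually consistent and physically meaningful.

## PIV with window deformation

Frames are CLAHE-equalized (8x8 tile grid, clip 0.01 — the parameter
conventions of MATLAB's adapthisteq, which the cited PIV tool wraps),
cropped to a 370x105 px ROI centered laterally with its top edge at the
median tracked surface row of a reference frame — by default frame 1,
but pipelines anchor at the first frame of the analyzed window, since
after compression the surface sits tens of pixels below its rest row
and an ROI anchored at the rest surface would spend the whole shear
phase in the weakly echogenic gel — and correlated pairwise: pass 1
at 64 px windows yields a predictor field (50% overlap); the second
frame is warped by the bilinearly interpolated predictor — with linear
extrapolation beyond the node hull, since clamping biases the outer
rows — and pass 2 at 32 px adds the correction. 370 px at 32 px windows
and 50% overlap gives 22 columns, matching the published grid width; no
single uniform overlap reproduces the published 12 rows at height
105 px (32 px windows at 50% give 5), so the row count is left
config-dependent.

Two numerical choices matter on log-compressed envelope speckle, whose
correlation peak is several pixels wide:

* the circular FFT correlation is divided by the per-lag overlap factor
  (the unbiased estimator); the raw estimator's loss-of-pairs taper
  shifts broad peaks ~0.5 px toward zero displacement;
* the peak-ratio validation excludes a radius-5 region around the
  primary peak (a 3x3 exclusion finds the peak's own shoulder as the
  "second peak"), with threshold 1.3; the normalized-median test uses
  threshold 4 rather than the customary 2 because on a 5-row grid a
  genuine shear gradient makes edge-row vectors differ from their
  (one-sided) neighborhoods by more than twice the local scatter —
  threshold 2 rejected correct vectors and biased the fitted gradient
  by ~8%, threshold 4 recovers it to ~2.5%.

Sub-pixel refinement is the 3-point Gaussian estimator with a parabolic
fallback on non-positive samples. Invalid vectors are masked and
infilled from valid neighbors; `surface_trace()` reads the top-row,
center-column node (closest to the dorsal surface, middle of the
array), `depth_profile_map()` averages each row laterally.

## Friction-phase analysis

`detect_friction_events()` takes the signed extremum of the surface
velocity within each stroke as the onset peak (under stick-slip it
falls at slip onset; in the pure-stick degenerate case the loading
velocity keeps rising and the extremum falls at the stroke end, making
the dynamic interval empty — which is why the search window is the
whole stroke rather than its first half) and the opposite-signed
extremum between stroke end and the end of the following rest as the
stop peak. Peaks below 3x the pre-shear standard deviation of the trace
are not reported. Durations are widths at half amplitude (the field
reports "amplitude and duration" without defining the latter; half
width is one admissible choice and is what the package means by
duration). Post-peak decays are fitted as log-linear least squares,
with non-decaying segments flagged rather than forced.
`classify_phases()` splits each stroke into a static interval [start,
onset peak] and a dynamic interval (onset peak, end]; on phantoms the
static duration matches `stick_slip_profile()` within 2 frames.
`young_modulus()` is the OLS slope of stress against strain restricted
to the 2.5–5% window where linear elasticity holds.

## Tolerances, degeneracies, determinism

* All tracking and PIV paths are deterministic: identical stacks and
  parameters give identical tables.
* Degenerate inputs fail loudly: empty bands refuse to initialize a
  contour, zero-variance windows are flagged invalid rather than
  throwing, all-flat gradient maps return zeros without dividing by
  zero, deformations that leave the frame abort rendering with a
  diagnostic.
* The snake's convergence tolerance is 0.5 px per sweep with at most 60
  sweeps per stage; the greedy scheme cannot capture interfaces beyond
  the smoothing basin (~3 sigma), which is why initialization always
  comes from the conditioned band.
* Test simulations are scaled down (shorter protocols, smaller frames)
  except the acceptance criteria that explicitly require the full
  1560-frame default sequence, which is rendered once and shared.

## Known limitations

The phantom's h/H-linear displacement profile is an assumption about
the artificial tongue, not a measured field; real PVA under large
compression is nonlinear. ToF is computed as two-way at a fixed
1540 m/s — sound-speed changes with compression are ignored. The PIV
validation thresholds were chosen on phantom speckle and may need
retuning for device data. The interactive anchor-point workflow of the
original contour tool is replaced by automatic initialization; no
graphical interaction is provided.
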