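---
title: "Describing unflattened photon beam profiles without a reference beam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Describing unflattened photon beam profiles without a reference beam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ufbeam)
```

## The problem

Removing the flattening filter from a linac head raises the dose rate
severalfold, but the resulting beam profile is conical rather than flat.
The conventional delineation of a flattened profile — field edges at the
50% level, penumbrae between 20% and 80%, everything normalized to the
central-axis (CAX) dose — breaks down for a cone: the CAX dose is no longer
representative of the dose near the field edge, so 50% of CAX lands in the
wrong place, and ever more wrongly as the field grows.

`ufbeam` implements a delineation that needs no flattened companion beam.
The key observation is that a collimated field edge is, to good
approximation, a sigmoid, and a sigmoid's inflection point sits at half the
local plateau dose. So:

1. locate, on each side, the position of maximum lateral gradient
   `|dD/dx|` (the inflection);
2. define the **reference dose** as **twice the dose at the inflection**;
3. apply the conventional fractions of that reference: field edges at 50%,
   penumbrae between 20% and 80%, the primary region as the central 80% of
   the field size, and the out-of-field region beyond 120% of it.

For a genuinely flat profile the inflection dose is half the plateau, the
reference equals the plateau, and the procedure reduces exactly to the
conventional one — that equivalence is the design claim, and it is what the
step-edge-equivalence tests assert.

## Numerical choices

* **Derivative estimation.** Central differences on the sampled profile,
  optionally after a moving-average smoothing (default 5 samples). Noise is
  amplified by differentiation, so smoothing applies *only* to inflection
  finding; all level crossings use the raw profile, where linear
  interpolation between the bracketing samples is robust.
* **Sub-grid refinement.** The discrete `|dD/dx|` extremum is refined by a
  3-point parabolic fit, giving sub-grid accuracy without assuming a
  profile model. The same refinement is used for the depth of maximum dose.
* **Ties.** Exactly equal slope maxima on one side (possible on
  piecewise-linear data or noise spikes in the tail) are an error by
  default; `tie = "first-from-center"` breaks them toward the field centre,
  because spurious slope spikes live in the tails.
* **Asymmetry.** The two side inflection doses are averaged into a single
  reference by default (`combine = "mean"`); `combine = "per_side"` keeps a
  separate reference per side for deliberately asymmetric fields. The
  primary and out-of-field fractions are taken about the field centre (the
  midpoint of the 50% edges) rather than the beam axis, which makes the
  delineation robust to mis-centred scans.
* **Interpolation.** Linear everywhere a dose level or position must be
  located between samples; this matches water-tank scanning practice and
  keeps every oracle analytic. All intervals are closed.

## Depth-dose metrics and curve comparison

Beam quality is specified by %dd(10)x, the photon component of the percent
depth dose at 10 cm; for nominal energies at or below 10 MV it equals
%dd(10) itself, which is the convention implemented (`pdd10x()` refuses
higher energies rather than silently skipping the lead-foil correction).
`find_dmax()` refines the discrete maximum parabolically and only warns —
rather than errors — when the maximum sits at the scan boundary, since
buildup scans may legitimately start below dmax. Surface dose is read at
2 mm, the shallowest depth a plane-parallel chamber scan reaches reliably.

Two comparison tools are provided: pointwise percent difference (in
percentage points of the normalized scale — a deliberate choice, recorded
here because "percent difference" is ambiguous) and a 1D gamma index.
Gamma uses global dose normalization (percent of the reference maximum),
default criteria 1%/1 mm, and minimizes over a dense linear resampling of
the evaluated curve (0.01 mm by default). The search window per reference
point is bounded by the gamma value at zero offset, which cannot exclude
the true minimizer; the tests check the implementation against an
exhaustive 0.001 mm brute-force minimizer.

## Scatter factors and off-axis ratios

`phantom_scatter()` removes the in-air collimator scatter from the total
scatter factor, Sp = Scp / Sc, and renormalizes all three columns to 1 at
the reference field (10 × 10 cm² by default). "Variation" across field
sizes is defined as the **range** (max − min); the range is the definition
under which the usual clinical summaries ("beam B shows x% less variation
than beam A") are simple arithmetic, and `relative_reduction()` implements
that comparison. Field sizes are square
side lengths; rectangular fields are out of scope.

`remove_divergence()` projects positions from the measurement depth to a
reference depth by similar triangles, assuming a point source at
`ssd + depth` from the measurement plane (fixed 100 cm SSD water-tank
geometry by default — the setup is configurable because it is rarely
recorded with the scan). OAR normalization happens *before* projection:
the off-axis ratio is defined per depth as D(x, d)/D(0, d), and the
projection then only decides which geometric ray the fixed off-axis
distance refers to.

## The synthetic generator

The generator exists to produce data with exactly the structural features
the analyses assume, under seeded randomness:

* **Profiles** are a lateral factor (a cone `1 − cone_slope·|x|` for
  unflattened beams, default 4%/cm; a flat top with optional 2% horns for
  flattened beams) times logistic edges, plus a constant out-of-field tail.
  Logistic rather than error-function edges were chosen so the penumbra
  (2·ln 4·w) and the inflection dose (half the local plateau) have closed
  forms usable as oracles. Multiplying a sigmoid by a sloped lateral factor
  shifts the product's inflection (at the inflection σ\* = ½ − w·g′/g), so
  the edge centres are offset by the closed-form amount that puts the
  50%-of-reference crossing exactly at ± field_size/2 — the generator's
  contract with the recovery tests. Default edge widths are 0.25 cm
  (flattened) and 0.30 cm (unflattened, reflecting the slightly wider
  penumbra of a quality-matched unflattened beam); default tails 3% and
  1.5% of the reference, reflecting the lower out-of-field dose after
  filter removal.
* **Depth-dose curves** use the minimal buildup-attenuation model
  `D(z) = (1 − exp(−a·z))·exp(−μ·z)`, whose two parameters are exactly
  identified from a (dmax, %dd(10)) pair by nested root finding. The
  default target pairs are (1.5 cm, 67.1) for the flattened beam,
  (1.3 cm, 63.8) for the energy-unaltered unflattened beam and
  (1.8 cm, 67.0) for the quality-matched one.
* **Frame series** emulate a linear diode array at 0.072 s per frame and
  0.5 cm spacing. The first frame(s) of each beam-on cycle are tilted
  linearly across the field (default 5% at the field edge) to emulate the
  beam-steering transient; per-point noise is multiplicative with relative
  standard deviation `noise_sd` (0.002 is a realistic diode-array frame
  noise and the value used in the stability tests). For gated delivery
  only beam-on frames are recorded, `ceiling(gate_window/frame_period)`
  per cycle — with the 0.5 s window and 0.072 s frames that is 7 frames,
  which is exactly the ramp-repetition period the stability analysis
  detects.
* **QA logs** are daily Gaussian output offsets (defaults mean 0.60%,
  sd 0.99%, n = 1354).

What the generator does **not** emulate: spectral changes and beam
hardening (the cone is depth-independent), scatter kernels, detector
volume averaging (measured penumbras on a real 0.125 cc chamber are
broadened by ~5 mm volume averaging; the generator's edges are the "true"
ones), setup errors, and servo dynamics beyond the first-frame tilt.
Passing tests therefore demonstrate that the *method* recovers the
constructed truth under realistic noise — not that any physical beam has
these parameters.

## Stability and QA analysis decisions

* Frame differences are computed after normalizing each frame **and** the
  reference to their own CAX value, so shape instability is isolated from
  pure output ramp-up; this normalization is recorded because profile
  stability plots rarely state it.
* Ramp detection excludes penumbra points (from `classify_regions` of the
  mean profile, padded by one detector spacing) and points where the
  reference is below 5% of its maximum: relative differences there measure
  noise and positional jitter, not beam state.
* A QA reading exactly at tolerance **passes**; "failing a 3% tolerance"
  means strictly exceeding it.
* `compare_variability()` uses a two-sided F test on the variance ratio as
  the default; it is a default, not an identification of the uniquely
  correct test, and the permutation check in the test suite confirms it is
  well calibrated on Gaussian QA logs.
* Symmetry offsets are consumed as already-computed percentages from the
  QA log. Computing symmetry from raw chamber readings of a 5-chamber
  device would need the vendor's formula, which is not standardized; a
  plain `100·(A − B)/(A + B)` per axis is a reasonable assumption but is
  deliberately not baked into the readers.

## Problem sizes

The test fixtures are deliberately desk-scale: profiles at 1 mm (down to
0.2 mm for closed-form checks) spacing over ±(0.6·FS + 5) cm, depth-dose
curves at 0.5 mm over 30 cm, frame series of 60–70 frames, QA logs of
~1350 records, and 50-case randomized property loops. These sizes are
chosen so the full suite runs in seconds while keeping every sub-grid
refinement and noise effect visible at the tested tolerances.

## Worked example

```{r example, eval = FALSE}
spec <- beam_spec("unflattened", field_size = 10, noise_sd = 0.003, seed = 42)
prof <- make_profile(spec, depth = 10)
classify_regions(prof, mode = "unflattened", tie = "first-from-center")

pdd <- make_pdd(spec)
c(dmax = find_dmax(pdd), pdd10x = pdd10x(pdd), surface = surface_dose(pdd))
```

## Known limitations

* Penumbra deconvolution for finite detector size is out of scope; widths
  from real chamber scans are upper bounds.
* The inflection method assumes one dominant sigmoid edge per side; MLC
  tongue-and-groove ripples or wedge profiles would need pre-smoothing
  beyond the default window.
* 1D gamma only; 2D/3D distributions and DICOM-RT inputs are not handled.
* The divergence projection assumes a point source; extended-source
  effects on the projected penumbra are ignored.
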