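---
title: "Quantifying delivery errors in fractionated pelvic IMRT: methods and design choices"
author: "fracdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying delivery errors in fractionated pelvic IMRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracdose)
```

## The problem

A fractionated IMRT course — here the whole-pelvis setting: 50.4 Gy
prescribed to the PTV in 28 daily fractions, delivered with a
dynamic-MLC technique — can miss its planned dose for three distinct
reasons:

1. **machine control**: the MLC leaves and the MU counter do not track
   their planned trajectories perfectly;
2. **residual setup error**: even after daily CBCT-guided repositioning on
   a 6DOF couch, a millimetre-scale rigid error remains;
3. **anatomical change**: weight change, bladder/rectum filling and
   transient rectal gas alter the radiological path lengths between the
   beams and the target from day to day.

`fracdose` implements one analysis per mechanism, plus a synthetic pelvic
phantom generator so the whole pipeline is exercised — and its mechanisms
tested quantitatively — without patient data. The per-structure readout
throughout is the DVH triplet D98% (near-minimum dose), D2%
(near-maximum) and Dmean, and differences are reported as signed percent,
planned minus delivered, normalised by the planned metric: positive
values are underdoses.

## Data model and geometry conventions

Volumes (`image_volume`, HU), doses (`dose_grid`, Gy) and ROI masks
(`structure_mask`) are axis-aligned voxel grids with voxel-centre
semantics: physical position = origin + 0-based index × spacing, all in
mm in the patient frame. The default dose grid resolution is 2 mm
isotropic, the conventional treatment-planning choice. Rigid transforms
(`rigid_transform`) are 3 translations (mm) + 3 rotations (degrees) about
the plan isocenter, composed in the fixed intrinsic order pitch → roll →
yaw; at the ≤ 2° angles of interest the order is immaterial, but a
convention has to be fixed for reproducibility.

Interpolation is trilinear for dose and HU and nearest-voxel for masks.
Out-of-grid dose reads return 0 Gy (dose supports are interior by
construction), out-of-grid HU reads return −1000 (air), and CBCT voxels
outside the reconstruction cylinder carry the sentinel −3024 so they can
never be confused with valid air. An exact identity transform
short-circuits to a bit-identical copy, a deliberate numerical choice
that lets the null pipeline produce literally zero differences (below).

Grids travel in a single-file portable container — a plain-text header
(kind, dim, spacing, origin, dtype, byte order) followed by the raw
little-endian array — with bit-exact round trips; registrations travel as
JSON. DICOM import/export is out of scope for this package: the analyses
are validated on generated data, and sites with DICOM data can convert to
the container with any standard toolchain.

## Trajectory-log analysis

A `trajectory_log` holds expected and actual per-leaf MLC positions (both
banks), cumulative MU, gantry angle and jaw positions at a fixed 20 ms
sampling interval. MLC error statistics pool the signed per-leaf,
per-sample differences (actual − expected) over both banks and all
samples; a moving-leaves-only filter is available but off by default,
since the choice is a reporting convention rather than physics. MU error
defaults to the mean ± SD of the *absolute* per-sample cumulative-MU
difference — a delivery lag is one-sided, and a positive mean with
SD of comparable size is the signature of a magnitude statistic — with a
signed variant behind a flag.

Aperture statistics come from the plan's control points: per control
point, the aperture area is the sum over open leaf pairs of gap × leaf
width with the gap clipped to the x-jaw window and pairs outside the
y-jaw window excluded; a pair is open when its clipped gap exceeds the
0.5 mm parked-gap threshold. The Millennium-120 leaf profile (40 central
5 mm pairs flanked by 2 × 10 outer 10 mm pairs) is built in; other MLCs
are described by a width vector. QA tolerances are always supplied by the
user's configuration (`tolerance_check()`), never hard-coded from any
guideline document.

The synthetic log generator interpolates a control-point sequence at the
machine sampling interval (rejecting sequences that would need leaf
speeds above 2.5 cm/s), then injects a Gaussian per-leaf position error
and an exponential-magnitude MU lag. The lag is drawn as per-block levels
(one level per ~100 samples) connected linearly, which keeps the actual
MU stream monotone — a log-file invariant — while preserving the
exponential law's mean; the effective sample size for recovery tests is
therefore the block count, not the sample count.

## Residual setup-error simulation

Setup error after image-guided repositioning is modelled as one static
rigid transform per simulated course — a residual *systematic* error —
with per-axis translation magnitudes uniform on [0, 2] mm and rotations
uniform on [0, 2]°, each with an independent random sign, rotations about
the plan isocenter. The protocol runs 28 simulations per case. The
planned dose is resampled through each transform ("dose blurring": the
isodose cloud moves, the anatomy does not, so no heterogeneity
correction applies), CTV D98%/D2% are read on the fixed CTV mask, and the
maximum absolute deviation over the simulations is the result, together
with the signed deviation at that worst simulation.

Two sampling-law details were genuinely open and are configurable: the
per-axis uniform law (default) versus a uniform-magnitude isotropic
vector law, which differ in their corner tails; and whether the reported
per-case number is the signed value at the maximum-|deviation| simulation
(our choice) or the maximum signed value. Both choices are recorded in
the result object along with the seed.

The geometric mechanism the simulation probes is margin coverage: the
synthetic plan's prescription plateau covers the PTV, which is the CTV
expanded isotropically by 7 mm. A ≤ 2 mm translation plus the ≤ ~2 mm
excursion that a 2° rotation produces at the CTV's extremities cannot
push any CTV voxel off the uniform plateau, so D98/D2 deviations stay at
interpolation-noise level; pushing `max_translation` beyond the margin
makes them grow monotonically. Both behaviours are asserted in the test
suite.

## CBCT-based daily dose

### Assembling the daily anatomy

Daily CBCT volumes cover a 26 cm-diameter cylinder that can truncate the
body outline. The daily density volume on the planning grid is assembled
per voxel: inside the FOV (evaluated in the fraction frame through the
online registration) the CBCT HU is read and converted with the *CBCT*
HU-to-density calibration; outside it the planning CT density is used.
Using one calibration curve per imaging chain is what neutralises the
CBCT's systematic HU offset. The dose calculation region is the body
outline expanded by 2 cm (exact Euclidean distance transform), so that
tissue gained or lost at the skin is inside the computed region; the
planning body contour is used for the region everywhere, a simplification
that matters little because the dose near the expanded boundary is
penumbral.

### The dose estimator

The engines used clinically (superposition/convolution
families) are out of scope here. `fracdose` declares a **primary-fluence
path-length perturbation model**: for each beam *b* with weight *w_b*,

$$ D_{daily}(v) \;=\; \sum_b w_b\, D_{plan}(v)\,
   e^{-\mu_{eff}\,\left(d_b^{daily}(v) - d_b^{plan}(v)\right)} $$

where \(d_b(v)\) is the radiological depth — the line integral of
relative electron density from the beam source to the voxel, computed by
uniform-step ray marching at half the minimum voxel spacing (or finer) —
and \(\mu_{eff} = 0.0035\,\mathrm{mm}^{-1}\) by default, the broad-beam
effective attenuation of a 10-MV photon beam in water beyond build-up
(≈ 3.5 %/cm; configurable). Beams are coplanar and equispaced (7 by
default, 9 selectable), equal-weighted, at 1000 mm SAD.

This model reproduces the first-order mechanisms exactly: 15 mm of extra
unit-density tissue upstream scales the target dose by
\(e^{-0.0035 \times 15} \approx 0.949\) (a ~5 % underdose), and a 20 mm
gas pocket upstream scales it by \(e^{+0.0035 \times 20} \approx 1.072\).
It does not model scatter-kernel deformation, spectral hardening or
output changes, so all claims made with it are mechanism-level, not
engine-equivalence.

One numerical choice deserves emphasis: the perturbation factor is
computed as \(1 + \sum_b w_b\,\mathrm{expm1}(\cdot)\), which is *exactly*
1 when the daily and planning depths agree. Identical anatomies therefore
reproduce the planned dose bit-for-bit, and every "difference" column of
a null course is exactly 0 — not 10⁻¹³ — which the tests assert with
equality.

### Fractions, accumulation and statistics

Each fraction is compared against the planned fraction dose (course plan
divided by the fraction count) per ROI after mapping the delivered dose
to the planning frame through the online registration. Fractions excluded
for data corruption carry a reason, are skipped in comparison, and the
accumulated dose is scaled by n_planned / n_included so it remains
comparable with the full-course plan — the normalisation had to be chosen
here, since comparing a 28-fraction plan with a 22–28-fraction delivery
record requires one. When the fraction doses come from the package's own
multiplicative estimator with identity registrations, accumulation
combines the per-voxel factors against the planned dose instead of
summing 28 resampled grids; this is the same algebra but exact in
floating point (sums of the all-ones null factors are exact integers).
Externally supplied fraction doses take the literal resample-sum-scale
path.

Deformable accumulation is supported only for *externally supplied*
deformation fields: `apply_deformation()` pulls the fraction dose back
through the per-voxel displacement field with trilinear sampling and no
Jacobian (energy) correction — a documented simplification. Registration
QA uses the Dice similarity coefficient, `2|A∩B|/(|A|+|B|)`. The analytic
test field is a uniform scaling warp about a centre, chosen over a
Gaussian-bump radial warp because its inverse is available in closed form
and oracle checks stay exact.

Planned-versus-delivered metric sets are compared with the classical
paired Student t test (two-sided, 5 % significance), delegating to the
standard implementation; zero-variance difference vectors are reported as
an explicit degenerate case rather than an undefined statistic. Fractions
whose CTV ΔD98% exceeds a configurable 2 % threshold are flagged in the
per-fraction report as replanning (ART) candidates.

## The synthetic phantom and what it does (not) emulate

The generator is deliberately minimal: an elliptical soft-tissue body
cylinder (semi-axes 115 × 85 mm), an ellipsoidal CTV (45 × 35 × 42 mm)
with the 7 mm PTV expansion done by exact distance transform, a spherical
bladder, a tubular rectum, spherical femoral heads (bone HU 700), on a
128 × 128 × 64 grid at 2 mm. The plan dose is a prescription plateau
exactly covering the PTV with a cosine penumbra falling to 50 % at 5 mm
outside it; it satisfies the three PTV planning goals (≥ 50 % at the
prescription, ≥ 95 % at 98 % of it, 0 % at 110 %) by construction, and
the tests verify that.

Daily variation models: radial body-contour change (systematic drift +
Gaussian noise per fraction; the default drift scenario reaches the
~1.5 cm change a visibly gained-weight fraction shows), stochastic rectal
gas pockets (15–25 mm), bladder filling scale, CBCT HU offset + Gaussian
noise, FOV cropping at 260 mm diameter, and a seeded residual
registration. With all magnitudes zero every fraction reproduces the
planning anatomy exactly.

What the phantom does *not* emulate — and what passing tests therefore do
not show about real data: anatomical realism (organ shapes, peristalsis,
true deformable motion), CBCT scatter/cupping artifacts (handled in
practice by the per-modality calibration, not simulated here), plan
modulation structure (the plateau is unmodulated, so blur-simulation
deviations are a lower bound tied to margin geometry rather than plan
complexity), and engine-grade dose physics. The analyses validated here
are the *mechanisms* — margin coverage, path-length perturbation signs
and magnitudes, random-error contraction under accumulation — not
clinical dose values.

## Problem sizes and numerical tolerances

The suite and the acceptance script run at sizes chosen to make each
check sharp but quick: the blur simulation runs on the full 2 mm phantom
(≈ 10⁶ voxels, 28 resamples, a few seconds); course-level tests use a
4 mm, 64 × 64 × 32 phantom over 28 fractions (≈ 25 s); mechanism tests
use a 5 mm slab world with a single beam and a 0.5 mm ray-marching step
so closed-form comparisons hold to 0.5 %; log-law recovery uses ≥ 10⁵
pooled leaf samples. The variance-contraction property is checked on 20
seeded courses with zero-mean random rigid per-fraction perturbations
(10 mm bound, beyond the 7 mm margin so fractional deviations are
nonzero), asserting contraction in ≥ 95 % of courses.

Numerical edge rules: D_q% uses exact voxel ranks with linear
interpolation between order statistics (the binned DVH curve is for
plotting/export only, default bin 0.05 Gy); ranks that are integer up to
floating-point round-off are snapped so that a percentage printed as
100·k/N lands back on rank k; relative differences divide by the planned
metric, with 0/0 reported as 0 % in course tables (the correct limit for
far-field OARs) while the strict API raises an undefined-ratio error;
resampled doses clamp tiny negative interpolation round-off to 0 Gy;
mask-distance queries on empty masks, empty ROIs entering a DVH, both-empty
Dice masks and single-pair t tests are errors, not silent values.

## Known limitations

Intrafraction (continuous) motion is not modelled — only the
interfraction snapshot that a daily CBCT represents. The dose estimator
is first-order in path length; large heterogeneity rearrangements
(e.g. gas adjacent to the target) also deform scatter kernels, which it
cannot see. Deformable registration itself is never computed, only
consumed. And the phantom's simplicity means figures produced here should
be read as mechanism demonstrations, not as predictions for any patient
population.
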