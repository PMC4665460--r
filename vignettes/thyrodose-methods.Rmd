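---
title: "Methods: simulated PET/CT thyroid quantification and dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated PET/CT thyroid quantification and dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrodose)
```

## The problem

Radioiodine accumulates avidly in the thyroid, which makes I-124 PET a
natural probe of thyroid physiology in small animals — and makes the
absorbed dose to the gland the first dosimetric quantity one needs. Two
measurement problems stand in the way. First, a rat thyroid (roughly
30–70 µL) is small compared with the resolution of a small-animal PET
scanner, so reconstructed counts spill out of any anatomically exact
region of interest (the partial-volume effect). Second, the absorbed dose
per decay depends strongly on the gland's mass, which varies between
animals, so a per-animal volume measurement — here contrast-enhanced CT —
is required to pick the right dose factor.

`thyrodose` implements the full chain for this experiment type:
a digital phantom and subject simulator, CT volume measurement,
spillover-compensated PET activity quantification, two-phase
time-activity-curve (TAC) fitting with closed-form time integration, and
an S-value based absorbed-dose calculation. Everything downstream of
acquisition is testable against analytic ground truth because the inputs
are simulated.

## Activity quantification: the X/Y/Z region scheme

Let Z be the anatomical thyroid outline drawn on CT and mapped onto the
PET grid (`n_z` pixels). Because of resolution blur, summing PET values
over Z alone underestimates the thyroid activity. The package therefore
uses an enclosing region X of fixed width (20 pixels by default) that
fully covers the gland plus its spilled counts, and an adjacent narrow
background band Y (7 pixels wide). With `A_x`, `A_y` the activities in X
and Y and `n_x`, `n_y` their pixel counts, the compensated thyroid
activity is

    A_thyr = A_x - A_y / n_y * (n_x - n_z).

The mean background per pixel, estimated in Y, is subtracted only over
the `n_x - n_z` pixels of X outside the outline: counts displaced out of
Z remain counted, ambient background is removed. Two properties follow
and are asserted by the test suite:

* **Exact recovery.** For an image equal to the true activity inside Z
  plus a constant background per pixel outside Z, the formula returns the
  true activity to machine precision.
* **Known bias.** If background is also present *inside* Z it is not
  subtracted there; the estimate overestimates by exactly that background
  times `n_z`. The package documents this bias rather than silently
  "fixing" a formula whose behaviour is the point.

Geometry choices that the formula's sources leave open were fixed as
follows. "Fixed width" is implemented as a 20-pixel-wide window per
coronal (fixed-y) plane, with a z height covering the mask plus a margin
and at least the window width (so a point-like gland gets a 20×20
window). The window is applied over the mask's coronal planes plus the
same margin of planes on each side: blur displaces counts along y too,
and a window that stops at the gland's own planes loses up to ~20% of the
activity of a 4 mm object at 2.6 mm FWHM. Y is placed laterally adjacent
to X, a one-pixel gap away, on the side away from the image center
(i.e. away from the trachea), and shares X's planes and z range.
A negative compensated activity (possible under noise) clamps to zero
with a flag, since activity is physically non-negative.

## CT volume and segmentation

CT is simulated as a unitless contrast index (air 0.0, water 0.1,
contrast agent 1.0) — no Hounsfield calibration is claimed. Where the
original workflow outlines the gland manually, the package uses a
reproducible automated stand-in: a global Otsu threshold (256-bin,
threshold at the optimal split-bin edge), removal of components below a
size floor, and retention of the up-to-two largest connected components
(the two lobes). Connected components are labeled in 3-D with
6-connectivity on a block-coarsened grid (4³ voxel blocks) for speed;
structures closer than about two blocks (~0.7 mm at CT resolution) could
merge, which is far below the anatomical separations simulated here.
Volume is exact arithmetic: voxel count × voxel volume (1 mm³ = 1 µL).

Masks move from the CT grid to the PET grid by majority-footprint
resampling: a PET voxel joins the mask iff more than half of its 4³
supersampled footprint maps inside the CT mask (identity transform for
synthetic data; a known rigid transform is accepted). Boundary-voxel
rounding is correlated around a convex surface, so mask volume is
preserved to about 2% for a 6 mm sphere, not to a single PET voxel.

## The synthetic data

**Phantom.** A 30 mm × 80 mm water cylinder holds three same-size pairs
of spheres (inner diameters 3.95, 6.23, 7.86 mm; fills 140, 198,
1765 kBq) at x = ±8 mm of a 3 mm air tube, one pair per axial level. The
sphere pairs sit at ±8 mm (rather than touching the tube) so that each
sphere's background band stays clear of its partner's blurred counts;
pair levels are separated by 20 mm. The manufacturer-style inner volumes
(31/125/250 µL) differ by 2–4% from the analytic volume π/6·d³ of the
printed inner diameters; the generator treats the diameter as ground
truth and reports analytic volumes (32.3/126.6/254.3 µL), keeping the
geometry self-consistent.

**Rasterization.** The true activity concentration (activity / analytic
volume, Bq/mL) is laid onto the PET grid (0.87 × 0.87 × 0.79 mm voxels)
by fractional-occupancy supersampling: voxels wholly inside/outside a
sphere are decided analytically, boundary-shell voxels are subdivided 4³
(configurable). Total activity on the grid matches the fill to well
under 0.5%. The CT material map uses 0.091 mm isotropic voxels; because
a whole-phantom CT grid would be enormous, the CT field of view defaults
to a tight box around the contrast structures (configurable), matching
how such images are cropped for analysis anyway.

**PET simulation** operates at the reconstructed, calibrated image level
(Bq/mL): a Gaussian blur of FWHM `sqrt(psf² + positron²)` with defaults
psf 1.7 mm and positron blur 2.0 mm — the scanner resolution is not
stated by the study this emulates, and the positron component is
motivated by the ~3.7 mm I-124 positron range in water — optionally
followed by Poisson noise applied in count space (sensitivity
5 counts/kBq·s, 2400 s frame) and rescaled. No attenuation, scatter,
randoms or dead-time modelling; scatter correction was likewise not
applied in the emulated workflow. CT noise is additive Gaussian
(default off in tests).

**Subjects.** The biological (decay-corrected) uptake curve is
`B(t) = C (1 - exp(-k_u t)) exp(-k_b t)`, scaled so its maximum equals
the subject's peak fractional uptake times the administered activity;
the measured activity is `B(t)` times the physical decay factor, with
multiplicative log-normal noise of chosen CV. The default cohort uses
the seven reference subjects' weights, administered activities
(0.70–21.50 MBq) and CT volumes, draws peak fractions uniformly in
4.0–6.2% (the observed range), `k_u` in 0.10–0.20 /h, and solves `k_b`
so the biological peak falls at 24 ± 2 h, sampling at 3/24/48/72 h. What
the generator does *not* emulate — body background activity, stomach and
bladder uptake, motion, registration error — bounds what passing tests
show about real data: they validate the arithmetic and the compensation
logic, not robustness to un-modelled physiology.

## Kinetics and cumulated activity

The published description of the TAC — "a sum of two equations, one for
uptake and one for outflow" — does not pin down a functional form. The
default here is the smooth two-rate model above, fitted to the physical
activities by bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`, physical decay fixed, deterministic
data-driven initialization); its rising and falling phases are the
uptake/outflow pieces. A piecewise alternative (linear rise from the
origin to the maximal sample, log-linear effective-decay fit on the
samples from the maximum on) is selectable and matches the
two-segment picture literally. Both integrate in closed form.

Cumulated activity integrates the **physical** curve — absorbed dose
arises from actual decays, so decay-corrected values would be wrong here,
while fractional-uptake plots do decay-correct to injection time; the
source material is silent on this and the dosimetrically correct reading
is used. For the smooth model, with `le = k_b + lambda_p`:

    A_tilde = 3600 · C · (1/le − 1/(k_u + le))   [MBq·s]

split at the physical curve's peak `ln(1 + k_u/le)/k_u` into uptake and
outflow parts that sum to the total exactly. The hour→second factor 3600
is applied exactly once, here. Integration extends to infinity by
default (standard practice for cumulated activity; no truncation error),
with a finite `t_max_h` available for sensitivity analysis. Closed forms
are cross-checked against adaptive quadrature to 0.01% in the tests.

A noisy-fit bias check is part of the acceptance suite: over 20 seeded
replicate cohorts at 5% measurement CV, the per-subject *mean* fitted
peak fraction must fall within ±0.5 percentage points of generator
truth. The mean (rather than every individual fit) is the stable
property: with four samples, three free parameters and 5% multiplicative
noise, individual fitted peaks scatter with ~0.2 pp standard deviation,
so a worst-of-140-fits criterion would hinge on single noise draws.

## Dosimetry

Absorbed dose is the MIRD-style self-dose product
`D[Gy] = A_tilde[MBq·s] × S[mGy/(MBq·s)] / 1000`, thyroid←thyroid only;
no cross-organ terms. The packaged S-value table holds the five distinct
(volume, S) pairs used in the reference study — (33.2, 0.70),
(43.4, 0.57), (47.3, 0.54), (51.3, 0.51), (69.8, 0.40) — at density
1.04 g/cm³; users may substitute their own CSV. Selection is by nearest
tabulated volume (the convention of the emulated study), with exact
distance ties broken toward the smaller volume, i.e. the larger,
conservative S-value; this tie-break matters for one reference subject
(49.3 µL is exactly 2.0 µL from both 47.3 and 51.3) and reproduces the
published assignment. Log–log interpolation is offered because nearest
lookup is discontinuous in volume. Dose per administered activity is
reported raw and rounded to the nearest 100 mGy/MBq for parity with the
conventional tabulation.

As a physics sanity check, a local-deposition estimate
`S_np = E_np · 1.60218e-13 / m` (E_np = 0.19 MeV of non-penetrating
energy per decay, the packaged default built from ~23% positron yield ×
~0.82 MeV mean positron energy) bounds the tabulated values from above:
positron escape from ~50 µL volumes keeps Monte Carlo S-values below
full local deposition. The packaged table sits at 79–95% of this bound.

## Numerical and reproducibility choices

* Coordinates: arrays indexed (x, y, z); voxel centers at
  `origin + (i − 1 + 0.5)·spacing`; coronal planes are fixed-y slices.
* Activity sums accumulate in sorted index order, making reports
  bit-reproducible for a given configuration and seed; pipeline outputs
  carry an MD5 hash of the canonical JSON serialization of their
  configuration plus the seed.
* Every stochastic stage takes an explicit seed derived from the run
  configuration's master seed; noiseless stages are deterministic.
* Test and validation problem sizes: phantom validation runs the full
  three-pair phantom at native PET resolution with per-sphere CT fields
  of view at native 0.091 mm resolution (~2–16 M voxel grids); kinetic
  recovery uses 20 replicate cohorts of 7 subjects. These sizes keep the
  whole suite under a minute while leaving boundary effects (blur
  conservation, segmentation shells) at realistic scale.

## Known limitations

* No scanner physics: sinograms, attenuation, scatter, randoms,
  dead time and reconstruction artifacts are all absent; the simulation
  starts at the calibrated image.
* The Eq.-style compensation leaves background inside the anatomical
  outline uncorrected (documented bias above).
* Registration is identity/known-rigid; real PET–CT alignment error is
  not modelled.
* The S-value table covers 33–70 µL rat thyroids only; nearest lookup
  clamps outside that range (and log–log interpolation clamps at the
  ends) rather than extrapolating.
* The local-deposition S estimate ignores photon self-dose and positron
  escape by construction; it is a bracket, not a dosimetry method.
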