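---
title: "Detector reference frames and systematic MLC errors in arc-therapy QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detector reference frames and systematic MLC errors in arc-therapy QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcqa)
```

## The problem

Volumetric-modulated arc therapy delivers radiation while the gantry
rotates, with the multileaf collimator (MLC) reshaping the beam at every
control point. Patient-specific QA compares a measured planar dose
against a reference, and the measuring device comes in two geometries: a
**gantry-stationary (GS)** detector such as a portal imager, which
rotates with the beam, and a **couch-stationary (CS)** detector such as
an ion-chamber array, which stays fixed like the patient.

`arcqa` simulates what each geometry reports when a *systematic* MLC
error — every leaf of bank A offset by 1 mm, the common calibration
tolerance — is injected into an arc plan. The interesting physics is
purely geometric: bank A stays on the same lateral side of a GS image
for the whole arc, but flips sides on a CS image whenever the gantry
crosses ±90°. A one-sided error therefore accumulates coherently in the
GS frame and is diluted across both sides in the CS frame.

## The model

### Plans and fluence

An arc plan is an ordered set of control points, each with an IEC 61217
gantry angle, an MU weight (normalized to sum to 1), and per-leaf edge
positions for the two banks: leaf pair *i* is open on the crossplane
interval [*Aᵢ*, *Bᵢ*] (cm at the isocenter plane), with *Aᵢ = Bᵢ*
denoting a closed, parked pair. Geometry uses 40 pairs of 1 cm projected
leaf width and a maximum 27 × 27 cm² field.

Each control point rasterizes to a unit-intensity fluence map on a square
isocenter-plane grid (exact partial-area weighting at aperture and leaf
band boundaries), optionally blurred by an isotropic Gaussian penumbra.
The frame transform is the identity for GS at every angle, and for CS a
mirror about the inplane axis, *x → −x*, when |θ| ≥ 90° (the boundary
angle is assigned to the flipped branch; a convention had to be fixed and
only its consistency matters). The plan dose is the MU-weighted sum of
transformed maps. Because the default per-angle deposition weight is 1,
both frames conserve the fluence integral exactly; an optional
|cos θ|^p weight is available for users who want lateral beams
attenuated, at the cost of that conservation.

Two idealizations are deliberate: all geometry lives at the isocenter
plane (no source–detector magnification or divergence), and there is no
scatter, phantom attenuation, energy response or imager glare. The
penumbra blur (default σ = 0.3 cm, applied once to the accumulated map —
the isotropic kernel commutes with the mirror, so this equals
per-control-point blurring) is the only concession to beam softness.

### The perturbation

`inject_bank_error()` shifts every **open** bank-A edge by the offset
(positive offsets open the bank: *Aᵢ → Aᵢ − d*), at every control point,
leaving MU weights, angles and bank B untouched. Closed pairs are treated
as parked under the backup diaphragm and stay closed; this keeps the
perturbed aperture area exactly `offset × leaf width × (number of open
pairs)` per control point. The operation is linear in the offset and
commutes with `collapse_gantry()`, which forces every angle to 0°
(static "collapsed" delivery) without touching the MLC.

### Comparison statistics

The headline statistic mirrors routine QA practice: the signed
percent-difference map 100·(D₀ − D₁)/N at identical detector positions
(DTA = 0), with N the maximum of the error-free map (Van Dyk global
normalization; local normalization is available), points below 10 % of
that maximum excluded, and the **threshold-to-95 %-match** defined as the
smallest dose-difference criterion δ at which 95 % of included points
agree. It is computed exactly as the ceiling order statistic of the
sorted |Δ| values — the k-th smallest with k = ⌈0.95 n⌉, which resolves
ties toward the smallest δ — and a 0.1 %-step scan of the pass-fraction
curve is kept both as an independent cross-check and as the exported
curve.

The gamma index is the standard combined dose/distance metric, computed
discretely over grid nodes with no sub-grid interpolation (determinism
and oracle-checkability were preferred; an interpolation refinement would
only lower gamma values). The search is restricted to three times the
distance criterion, which is exact because the matched-position candidate
already bounds γ by the pure dose term. Tests verify equality with an
exhaustive all-points search.

DVH metrics use the discrete convention D*ₚ* = the largest dose received
by at least a fraction *p* of the ROI (a descending order statistic), and
V*ₓ* = the fraction of the ROI at or above *x*; both are exactly testable
by enumeration. Reported per ROI: D95 (coverage), D1 % (near-maximum),
mean dose, and V107 % of prescription (hot spot). Relative differences
are reported unsigned with the error-free value as denominator and the
direction kept separately, since a signed convention is ambiguous when
metrics can move either way. Planar ROIs stand in for volumetric
structures; the metric formulas are dimension-agnostic.

## The synthetic plans

No clinical plan data ship with the package; a seeded generator produces
single full arcs with the structural features the mechanism needs:

* 72 control points equally spaced over −170° → +170° (a single arc);
* a contiguous block of 16–24 open leaf pairs near the field center;
* per-leaf aperture centers and widths evolving as clipped Gaussian
  random walks (initial spread 1.5 cm, mean width 6 cm, minimum gap
  0.5 cm), bounded by a 0.5 cm maximum edge travel per control point so
  adjacent apertures are physically plausible;
* log-normal MU weights (σ = 0.5), normalized;
* a central **target corridor**: open pairs within 5.5 cm of the inplane
  axis never close across |x| < 2.5 cm, mimicking optimizer-driven
  apertures that conform around the planning target. This guarantees the
  synthetic target ROI lies inside the union aperture footprint and
  receives a stable high dose.
* edges stay 1.5 cm clear of the ±13.5 cm travel limit so that millimeter
  perturbations can never push a leaf out of range.

These defaults were chosen once as a plausible stand-in for modulated
head-and-neck/esophagus arcs; they are *not* clinically optimized plans.
What passing tests demonstrate is the reference-frame mechanism and the
correctness of the statistics — not absolute clinical error magnitudes,
which depend on real plan modulation, detector response and measurement
noise that this package does not model. In particular the absolute
thresholds reported by the simulation are smaller than published
measured values for real plans (idealized unit fluence has no
out-of-field dose, no detector noise, and gentler modulation); the
*orderings* and the GS/CS ratio are the reproducible content.

ROI masks (one central target ellipse, two lateral organ ellipses) are
generated per seed on the analysis grid and are deterministic.

## The experiment

`run_experiment()` mirrors an eight-patient measurement campaign. Per
seed: generate the plan, make the MLC0PE/MLC1PE pair, collapse both,
accumulate GS-rotational, CS-rotational and CS-collapsed doses at 0.05 cm
resolution, then sample each arm with its detector model:

* the GS arm as a fine-resolution imager analyzed on the 0.3 cm grid
  (`analysis3mm`);
* the CS arms as a 729-chamber array — 1 cm center-to-center pitch with
  0.5 cm square volume averaging (`array729`).

The detector assignment matters and is a deliberate default. With *both*
arms analyzed on the same 0.3 cm lattice the simulation isolates the pure
frame geometry, and the GS/CS threshold ratio settles near 1.5 — which is
also where the same-detector comparison (CS-collapsed vs CS-rotational,
both measured by the array) sits. The published twofold GS/CS contrast
involves a second ingredient on top of the geometry: the gantry-mounted
imager samples the plane two orders of magnitude more finely than a
chamber array, whose 0.5 cm volume averaging flattens the narrow error
strips. With each arm sampled by its own detector model the simulated
ratio of mean thresholds is ≈ 1.9 over the default seeds. Users can set
`gs_detector`/`cs_detector` to the same spec to recover the pure-geometry
reading.

Gamma analysis (2 %/2 mm and 3 %/3 mm on the CS rotational pair) and DVH
scoring run on the 0.3 cm analysis grid; the DVH prescription is
normalized so the reference target D95 equals it, the usual coverage
convention, making the V107 % hot-spot volume a nontrivial quantity.

Grid sizes are a speed/fidelity compromise chosen for the study: 0.05 cm
simulation resolution resolves the 0.1 cm error strips with exact
partial-area weighting (finer grids change thresholds by far less than
the seed-to-seed spread), and 0.3 cm is the analysis resolution typical
of planning-system exports and QA software. The unit-test suite runs the
orchestration layer at coarser resolution (0.15–0.25 cm); the acceptance
checks of the mechanism itself use the full setting.

## Numerical choices and degenerate inputs

* Grids are square, centered, with an odd node count so a node sits on
  the beam axis; mirroring is then an exact column reversal with no
  interpolation.
* Comparisons require bit-identical grids and refuse to resample
  silently; area-averaging requires the dose pitch to be no coarser than
  the detector element.
* Pass/fail comparisons (`|Δ| ≤ δ`, `γ ≤ 1`) carry a 1e−9 absolute guard
  against floating-point representation of decimal percentages.
* An all-closed control point rasterizes to a zero map; an open aperture
  entirely outside the grid is an error, as are empty ROIs, empty
  inclusion masks, and perturbations that would push an edge past
  ±13.5 cm or through the opposing bank.
* A zero denominator in a DVH relative difference yields a flagged
  `NA`, never a number.
* All randomness is seed-threaded through a helper that restores the
  caller's RNG state, so identical configurations reproduce identical
  reports (the provenance block records the seeds and an MD5 of the
  serialized configuration).

## Known limitations

Beyond the stated idealizations (no scatter/attenuation/response, planar
ROIs, unit fluence): the simulation cannot reproduce absolute published
error magnitudes, only orderings and ratios; the CS mirror is a binary
flip rather than a continuous projection through a phantom, so angles
near ±90° — where a real lateral beam traverses the detector plane
edge-on — are the least physical regime; and closed-pair leakage,
tongue-and-groove and jaw effects are absent. These do not affect the
one-sided-accumulation mechanism, which is the package's subject.
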