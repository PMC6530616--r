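---
title: "Simulating MVCT imaging dose on a helical tomotherapy unit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating MVCT imaging dose on a helical tomotherapy unit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvctdose)
```

## The problem

On a helical tomotherapy unit, every treatment fraction starts with a
megavoltage CT (MVCT) scan for patient positioning. The imaging beam is the
treatment beam detuned to a nominal 3.5 MV, collimated to a single
400 × 4 mm field at a source–axis distance (SAD) of 85 cm, delivered
helically while the couch travels. Over tens of fractions the accumulated
imaging dose to organs is not negligible — of the order of 1–2 cGy per scan,
tens of cGy over a course, i.e. around one percent of a typical
prescription. `mvctdose` models this delivery end to end: beam model,
delivery discretization, 3D dose, output calibration, and organ-level
reporting.

## Delivery model

The machine exposes three pitches, defined by couch travel per 10 s gantry
rotation: fine 0.4 cm, normal 0.8 cm, coarse 1.2 cm. A helical scan of
length $L$ takes

$$T = \frac{L}{\text{couch travel per rotation}} \times 10\ \mathrm{s},$$

and time maps to monitor units by the bookkeeping convention 60 s = 40 MU
(`time_to_mu()`; the constant is configurable because it is a convention,
not a physical property of the unit).

The continuous helical delivery is discretized
(`build_helical_plan()`) into $n = L / \Delta$ beams at cell-centered
isocenters spaced $\Delta = \text{travel} / \text{beams per rotation}$
along the couch axis, with gantry angles advancing by
$360^\circ/\text{beams per rotation}$ (default 8, i.e. 45° steps). The
total MU is shared equally among the beams, so the total dose is
invariant under angular refinement. A 4.8 cm scan at normal pitch yields
48 beams of 60 s / 40 MU total; fine and coarse give 120 s / 80 MU and
40 s / 26.7 MU. Static plans (`build_static_plan()`) fix the gantry angle
and assign each beam the MU of $\Delta / v_\text{couch}$ seconds.

The dose of a plan is the superposition of its discrete beams:

$$D(\vec{x}) = \sum_{i=1}^{n} D^{400\times4}_i(\vec{x}; \vec{a}_i, g_i, \mathrm{MU}),$$

with $\vec{a}_i$ the isocenter and $g_i$ the gantry angle of beam $i$.

## Beam model

A beam is characterized by three measured curves: the percentage depth
dose PDD($d$) along the central axis, and two off-center ratios,
OCR$_x$ (lateral) and OCR$_y$ (longitudinal), measured at 1.5 cm depth.
Curves load from two-column CSV (`read_profile_csv()`), are normalized
once at load (`normalize_curve()`: PDD to its maximum, OCRs to their
central value), and are evaluated by piecewise-linear interpolation with
clamped extrapolation — beyond the last node the terminal value is held,
which avoids negative dose and makes far-field behaviour explicit (a
terminal zero node forces a zero tail). Film-scanned commissioning data
are dense (75 dpi), so higher-order fits would add penumbra overshoot
risk without accuracy benefit.

Two modelling assumptions are worth stating explicitly:

* **Separability.** The 2D field factor is OCR$_x(x)\,$OCR$_y(y)$. The two
  profiles are measured independently and no 2D fluence map is available,
  so a separable ansatz is the only supportable choice.
* **Profile-shape invariance with depth.** The OCRs measured at 1.5 cm
  are applied at all depths after geometric back-projection of the
  off-axis position to the isocenter plane. No depth-resolved profiles
  exist for this field.

### The synthetic generator

`synthesize_beam_model()` builds a fully analytic model so the whole
pipeline is testable without machine access. The PDD is
$(1 - e^{-k d/d_\max})\,e^{-\mu d}$ sampled on a 0–35 cm grid, with $k$
solved so the maximum falls exactly at the build-up depth $d_\max$; each
OCR is a flat top with an error-function penumbra. Defaults, chosen once
from the physics of a ~3.5 MV imaging beam:

| parameter | default | rationale |
|---|---|---|
| `buildup_depth` | 1.0 cm | d$_\max$ of a ~3.5 MV beam, upstream of the 1.5 cm reference depth |
| `attenuation_coeff` | 0.055 cm⁻¹ | effective attenuation matching measured central-axis ratios over 4.5–25 cm depth in a 30 cm cylinder |
| `penumbra_sigma_x` | 0.3 cm | film-resolved penumbra of the 40 cm jaw edge |
| `penumbra_sigma_y` | 0.1 cm | gives a longitudinal FWHM of exactly 0.4 cm with soft shoulders, as film measurements of this field show |

OCR tail values below $10^{-12}$ of the central value are truncated to
exact zero; this bounds the neglected dose at the $10^{-12}$ level and
lets the engine skip voxels with no longitudinal field weight, which is
what makes full-resolution plans tractable.

The generator emulates the *shape* of commissioned curves, not any
specific machine's output: absolute dose levels, scatter-driven
scan-length effects beyond the profile tails, and film-digitization
artifacts of real commissioning data are outside what passing tests on
the synthetic model demonstrate.

## Dose engine

`compute_beam_dose()` evaluates, at every voxel center,

$$D = \mathrm{MU} \cdot C \cdot
\frac{\mathrm{PDD}(d_\mathrm{rad})}{\mathrm{PDD}(d_\mathrm{ref})} \cdot
\mathrm{OCR}_x(x_\mathrm{iso}) \cdot \mathrm{OCR}_y(y_\mathrm{iso}) \cdot
\left(\frac{\mathrm{SAD}}{z}\right)^2,$$

where $d_\mathrm{rad}$ is the radiological depth — the density-weighted
path length from source to voxel, computed by exact Siddon voxel
traversal — $x_\mathrm{iso}, y_\mathrm{iso}$ are the off-axis
coordinates back-projected to the isocenter plane, and $z$ is the source
distance *measured along the beam axis*, so the inverse-square factor is
exactly 1 everywhere on the isocenter plane and the off-axis
back-projection is a pure fan scaling. $C$ is the output calibration
factor (cGy/MU). Radiological depth makes the engine consistent in
heterogeneous media: in a half-density slab the dose at geometric depth
$d$ equals the water dose at $d/2$ up to the inverse-square difference,
a closed form the test suite checks.

This is a factorized primary-beam engine, not a convolution/superposition
algorithm: there is no lateral scatter kernel. The properties the package
is validated on — MU linearity, superposition, pitch and couch-speed
scaling, rotational symmetry, angular-refinement convergence, geometric
and heterogeneity consistency — are all preserved by the factorization.
What is *not* fully represented is the scan-length dependence of phantom
scatter (a few percent effect at these field sizes), which enters only
through the measured profile tails.

Numerical choices: dose is accumulated in double precision at voxel
centers (no sub-voxel sampling; the 0.25 cm default spacing against the
0.4 cm field length is the accuracy driver, and the angular-refinement
test covers it); voxels of air with zero upstream density receive no
dose; a beam contributes nothing behind its source.

## Output calibration

`calibrate_output()` reproduces the reference workflow: the reference
scan (6 cm static scan at 0.1 cm/s, gantry 0°, 30 beams at 0.2 cm
intervals, 40 MU) is computed on the split cylindrical phantom with
$C = 1$, the dose is read at the chamber position (1.5 cm depth,
0.44 cm longitudinal averaging emulating the A1SL collector), and

$$C = \frac{D_\mathrm{meas}}{D_\mathrm{cal,\,1\,cGy/MU}}.$$

Recomputing the reference plan with the calibrated model returns the
measured dose exactly (linearity makes the calibration a fixed point).
Point doses are read by trilinear interpolation; chamber-style readings
average at least 9 samples along a centered IEC-Y segment.

## Phantoms, reporting, conventions

Phantom generators (`make_cheese_phantom()`, `make_slab_phantom()`,
`make_hetero_phantom()`) rasterize by voxel-center membership — the
simplest unambiguous rule at the ≤ 0.25 cm spacings used. Air is density
0 rather than 0.0012: with radiological-depth scaling the difference is
below 0.1% at phantom scales. The coordinate frame is IEC-flavoured:
`y` is couch travel, `z` vertical (gantry 0° enters from +z), `x`
right-handed; world coordinates are continuous cm from the grid corner,
voxel indices 1-based.

Reporting follows the clinical convention for imaging-dose tables:
per-organ maximum voxel dose per fraction (`organ_max()`; a point max,
not a near-max like D0.03cc), total over the fractionation, and percent
of the prescribed dose (`build_report()`). Internals stay unrounded;
printing rounds to 2 decimals, and `summarize_reports()` averages
display-rounded columns because published tables are averaged that way —
reproducing a table's printed average requires averaging its printed
cells. DVHs (`compute_dvh()`) use the cumulative volume-fraction ≥ dose
convention with voxel-count weighting.

## Problem sizes and determinism

The delivery-scaling analyses run on the 30 cm × 18 cm cylindrical
phantom at 0.25 cm spacing (120 × 72 × 120 ≈ 1.0 M voxels), the
resolution needed to resolve the 0.4 cm field; structural property tests
use 20³–130 k voxel grids where the property is resolution-independent.
The rotational-symmetry check runs at the working 0.25 cm resolution
because coarser lattices alias the longitudinal beam comb against the
voxel grid. Everything in the package is deterministic: phantoms, plans
and the synthetic beam model involve no randomness, so identical inputs
give bitwise-identical outputs.

## Known limitations

* No lateral scatter kernel (see above); absolute agreement with
  measured data at the 2–3% level where scatter conditions change is
  outside the engine's design envelope.
* Couch and bore attenuation are not modelled.
* The initial gantry angle and rotation sense of a real acquisition are
  not exposed by the unit; both are configurable and default to 0° /
  counter-rotation-free conventions, which is irrelevant on rotationally
  symmetric phantoms but matters for single-beam geometries.
* No DICOM import/export: phantoms and doses exchange as ASCII NRRD,
  masks as JSON index lists, beam models as JSON, plans as YAML/JSON.

## A worked example

```{r example, eval = FALSE}
model <- synthesize_beam_model()
phantom <- make_cheese_phantom()            # 30 cm x 18 cm, 0.25 cm voxels
plan <- build_helical_plan(-2.4, 4.8, "normal")

# calibrate against a (here: hypothetical) chamber reading of 1.33 cGy
split <- make_cheese_phantom(split = TRUE)
chamber <- poi(c(0, 0, 13.5), averaging_length = 0.44)
model <- calibrate_output(model, build_static_plan(-3, 6, 0.1),
                          split, chamber, measured_dose = 1.33)

dose <- compute_plan_dose(phantom, plan, model)
organ <- add_cylinder_mask(phantom, "core", c(0, 0, 0), 4, 2)
fx <- fractionation(180, 33)
build_report("core", organ_max(dose, organ), fx)
```
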