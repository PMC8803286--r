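---
title: "Modelling dose robustness to tissue-expander port motion"
author: "expanderRobust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dose robustness to tissue-expander port motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During postmastectomy radiotherapy with a temporary tissue expander in
place, the expander's metal injection port — a magnet core inside a titanium
shell — sits in the middle of the target volume. Two things are awkward
about it. First, it is dense enough (nominal 8.0 and 4.0 g/cm³) to cast a
measurable dose shadow, so planning systems override its voxels with those
nominal densities rather than trust artefact-ridden CT numbers. Second, it
does not stay put: daily imaging shows inter-fractional displacements of up
to 17 mm, with 87% of 3-D deviations below 5 mm. The question this package
addresses is how much those displacements perturb the *cumulative* dose in
the tissue most at risk of recurrence — the thin shell abutting the implant
— and whether the answer depends on the delivery technique (tangential
parallel-opposed fields, a 230° conformal arc, or helical-like fan-beam
delivery).

Two error classes are modelled separately. An **internal port error (IPE)**
moves the port *inside* the anatomy (expander migration, anatomy change):
densities are edited in place, beams stay fixed. A **patient registration
error (PRE)** moves the whole patient relative to the beams: the anatomy is
untouched and every beam isocentre is shifted instead. Each class is run in
a **daily-variable** scenario (one independent shift per fraction, summed)
and a **systematic** scenario (one persistent large shift, scaled by the
fraction count). A final scenario overrides the port with tissue-equivalent
density to quantify the error made by ignoring it at planning time.

## The phantom

No public CT data exist for this setting, so the package generates a
synthetic thorax at ellipsoid/cylinder fidelity: an extruded elliptical
trunk with a spherical breast mound, a saline implant (sphere, default
radius 35 mm), the port (magnet-core cylinder in a coaxial titanium shell,
axis anterior–posterior — the true port geometry is not published, so the
dimensions are configurable assumptions), an ipsilateral lung, a heart, a
rib shell around the lung and a 3 mm skin rind. Default grid:
128 × 128 × 64 voxels at 2.5 mm isotropic — fine enough to resolve the 5 mm
ROI shell and 17 mm shifts, small enough that a full scenario matrix runs in
minutes. The PTV is the 5 mm expansion of the implant/chest wall truncated
at the skin and at the ribs/lung. Every voxel carries exactly one tissue
density (air < lung < breast ≤ saline < rib < titanium < magnet); the heart
is assigned the water-equivalent soft-tissue value. The HU→density
calibration is a piecewise-linear anchor table carrying (−1000, 0.001),
(0, 1.0), (3926, 4.0) and (10248, 8.0); the two metal anchors are not
collinear with the water point, which is why a table, not a slope, is used.

`laterality = "right"` mirrors the default lateral geometry across the
midsagittal plane. Because all shapes are quadric level sets evaluated at
voxel centres on a grid symmetric about the origin, mirrored configurations
produce exactly mirrored masks — a property the tests exploit.

What the phantom does *not* emulate: realistic anatomy, tissue
heterogeneity texture, breathing motion, deformation, or the artefact
physics of metal in CT (simulated artefacts are simple multiplicative
streaks used only to exercise the correction). Passing tests therefore
demonstrate the *mechanics and directions* of the robustness analysis, not
patient-specific percentages.

## The dose engine

The commercial collapsed-cone / Monte Carlo / convolution–superposition
engines are out of scope. The stand-in is deliberately simple and fully
documented:

dose(v) = w · inAperture(v) · (SAD / d(v))² · exp(−μ_w · rp(src, v)),

followed by an isotropic Gaussian scatter blur. Here rp is the *exact*
Siddon voxel-traversal radiological path (g/cm²) from the source to the
voxel, μ_w = 0.049 cm²/g is a 6 MV-like attenuation coefficient per unit
mass density, SAD = 1000 mm, and the blur σ defaults to 5 mm. Key
approximations, in order of importance:

* attenuation scales with mass density only — crude for high-Z alloys, but
  it reproduces the qualitative port shadow, and every endpoint is a
  *difference* between perturbed and reference runs of the same engine;
* no electron-transport buildup; dose ≈ primary TERMA + Gaussian scatter;
* arc and helical beam weights are uniform (no inverse optimisation);
  conformality comes from per-angle PTV apertures and plan quality from the
  D90 normalisation. Hotspots are therefore larger than clinical plans
  would show; robustness *ordering* is unaffected, absolute DVH values are
  not to be compared against clinical constraints.

The engine is linear in beam weight to machine precision, beam doses
superpose, and adding material along a ray can only decrease the pre-blur
dose distal to it — the three invariants the test suite checks explicitly.

Plan geometry defaults: the tangents are two half-blocked parallel-opposed
beams whose shared posterior edge is the plane through the isocentre; the
isocentre sits 15 mm behind the posterior PTV border (`blockMargin`),
mirroring the 1.5–2 cm of lung conventionally included in deep tangent
fields so the chest wall is clear of the penumbra; the anterior edge
extends 20 mm of flash beyond the skin. The arc uses 47 beams over exactly
230° centred on the implant direction with 5 mm conformal margins; the
helical emulation uses 32 angles per rotation, a 25 mm fan, and isocentre
steps of half the fan width across the PTV extent.

## The error model

The measurements behind the model are per-axis ranges (lateral
[−17, 11] mm, vertical [−10.8, 7.0] mm, longitudinal [−8.0, 7.0] mm) and a
single distributional statistic: 87% of 3-D deviations below 5 mm. Any
distribution matching those is admissible; the package uses the minimal
calibratable choice — per axis, a zero-mean two-component Gaussian mixture
(σ_s = 1.5 mm for the usual small wobble, σ_l = 6 mm for occasional large
excursions), truncated to the measured supports. The large-component weight
p is solved deterministically (uniroot on a midpoint-rule quadrature of the
3-D sub-5-mm probability), giving p ≈ 0.129; because the calibration is
analytic, sampled series hit the 87% target to within Monte-Carlo noise for
any seed. The systematic scenario defaults to the largest measured
single-axis bound applied along its axis (−17 mm lateral); whether the
original large error was single-axis or a 3-D vector is unstated, so the
shift is configurable and recorded in the run manifest.

PRE is realised as a beam-isocentre shift of −d rather than resampling the
patient grid: the cumulative dose then lives natively in the planning
anatomy with no interpolation artefacts. The equivalence with the
resampling realisation is *tested*, not assumed (they agree to well under
1% of prescription away from the grid boundary for voxel-multiple shifts).

## Accumulation

Per-fraction dose is the full plan dose scaled by 1/25 — uniform
fractionation, and exactly equivalent to a true 2 Gy calculation under a
linear engine. Fractions whose effective shift is identical (always true
for systematic series, common after voxel rounding for IPE) share one
full-weight calculation scaled by their multiplicity. This is exact under
linearity, faster, and gives two identities *by construction*: an all-zero
daily series reproduces the reference dose bit for bit, and a constant
daily series reproduces the systematic scenario bit for bit. IPE doses are
computed on the per-fraction edited grid but reported on the planning
anatomy — voxel correspondence is exact because IPE edits densities in
place. Vacated port voxels are backfilled with saline inside the implant
and the mean breast density elsewhere (the source data are silent on
backfill; this choice avoids creating spurious air cavities).

## Metrics

The ROI is the 5 mm Euclidean dilation of the implant, intersected with the
PTV, minus the implant interior ("tissue abutting the implant"), restricted
to the z-slices where the port is present including the extreme slices it
migrates to. Dilation is performed in mm space with a structuring element
inflated by a quarter voxel: both the mask surface and the candidate voxels
are rasterized, so the centre-to-centre criterion is biased by roughly half
a voxel split between the two; the quarter-voxel correction brings the
dilated shell within a few percent of the analytic volume (the test suite
checks a 30 → 35 mm spherical shell). Whether the clinical "implant"
contour includes the port volume is ambiguous in the source; the full
implant sphere is expanded here.

DVH conventions: V_x counts voxels with dose ≥ x (≥ at the threshold);
D_x is the minimum dose of the hottest ⌈x%·n⌉ voxels; percentiles of
point-dose differences use linear interpolation between order statistics
(R's type-7 quantile), stated explicitly because the source does not give a
convention. All dose differences are normalized to the 50 Gy prescription.
OAR metrics (ipsilateral lung V20Gy, heart V5Gy) are computed on masks
zeroed outside the ROI's slices.

## Numerical choices and degenerate inputs

* Mask translation uses nearest-voxel rounding (no interpolation): masks
  are boolean and shifts are measured port-centre displacements; the
  rounding error is at most half a voxel (1.25 mm by default).
* Normalisation scales all beam weights by one factor so PTV D90 equals the
  prescription; under the linear engine the rescaled D90 is exact, and the
  factor halves when all input weights double.
* Empty ROIs are returned with a warning (not an error); empty PTVs,
  missing masks, out-of-body port shifts, unnormalized plans, and
  mismatched grids all raise typed errors naming the violated condition.
* The Gaussian blur renormalises its kernel at the grid boundary so no
  dose mass is invented outside the grid.
* Segments outside the grid contribute zero radiological path; a beam
  whose aperture is empty while its weight is positive is rejected at
  construction.

## Problem sizes used by the tests

Module-level tests run on a 64 × 64 × 32 grid at 5 mm (with the port
enlarged so its shell is resolved at that pitch); the end-to-end robustness
properties run on the default 2.5 mm phantom, and the PRE dual-realisation
check on a 128³ grid. These sizes were chosen so the whole suite completes
in a few minutes while every property is exercised at the default geometry
at least once.

## Known limitations

Absolute DVH values are not clinical: no buildup, no optimisation, simple
scatter. The error model is a calibrated stand-in constrained by ranges and
one probability statement, not a fitted per-patient distribution; the
optional per-patient systematic offset needed to emulate outlier cases is
off by default. Rotational and deformable port motion, intra-fraction
motion, image-registration measurement error, and re-optimisation per
fraction ("planned adaptive" workflows) are all out of scope. Results on
the synthetic phantom demonstrate directions and orderings — the daily
averaging-out, the cost of systematic errors, the override bias, and the
technique ordering — not patient-specific magnitudes.
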