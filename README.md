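# expanderRobust

Postmastectomy breast radiotherapy is often delivered while a temporary
tissue expander — a saline implant with an embedded metal injection port (a
magnet core inside a titanium shell) — is still in place. The port is a
small, very dense object that casts a dose shadow, and its position varies
from fraction to fraction, both because the port moves inside the patient
(internal port error, IPE) and because the whole patient is set up slightly
differently each day (patient registration error, PRE). `expanderRobust`
simulates how these inter-fractional errors perturb the cumulative dose for
three delivery geometries — tangential parallel-opposed fields, a partial
(230°) conformal arc, and a helical-like full-rotation fan beam — and
quantifies the perturbation with DVH and point-dose-difference metrics in
the clinically meaningful shell of tissue around the implant.

## What it does

* **Synthetic phantom** (`generatePhantom`): a thorax-like voxel phantom
  (body, ipsilateral lung, heart, rib shell, saline expander, metal port)
  with one physical density per voxel; HU-to-density conversion via a
  piecewise-linear calibration that carries the extended-scale metal anchors
  (HU 3926 → 4.0 g/cm³, HU 10248 → 8.0 g/cm³).
* **CT editing** (`correctArtefacts`, `overridePortDensities`, `shiftPort`,
  `overridePortAsTissue`): artefact-slice correction with the mean breast
  density, nominal metal overrides, rigid in-anatomy port shifts with
  background backfill, and the ignore-the-port tissue override.
* **Dose engine** (`computeBeamDose`, `computePlanDose`): a simplified,
  fully documented divergent-beam model — inverse square × exponential
  attenuation along exact Siddon radiological paths (μ/ρ = 0.049 cm²/g)
  followed by a Gaussian scatter blur (σ = 5 mm). It is a stand-in for
  commercial engines, built for *relative* robustness comparisons, not
  absolute dosimetry.
* **Plans** (`makeTangentialPlan`, `makeArcPlan`, `makeHelicalPlan`,
  `normalizePlan`): half-blocked parallel-opposed tangents with anterior
  flash, a 47-beam 230° conformal arc, a fan-beam full-rotation emulation;
  all normalized so PTV D90% equals the 50 Gy / 25 fraction prescription.
* **Error model** (`defaultErrorDistribution`, `sampleErrorSeries`,
  `systematicShift`, `applyPre`): per-axis truncated two-component Gaussian
  mixtures on the measured supports (lateral −17…11 mm, vertical
  −10.8…7.0 mm, longitudinal −8.0…7.0 mm), calibrated so 87% of 3-D
  deviations are below 5 mm; daily-variable and systematic scenarios for
  both error classes.
* **Accumulation and metrics** (`runReference`, `runDaily`, `runSystematic`,
  `runOverride`, `buildRoi`, `dvhValue`, `pointDoseStats`, `buildReport`,
  `runPipeline`): cumulative dose in the planning anatomy, the 5-mm
  peri-implant ROI restricted to port slices, V100%Rx / V20Gy / V5Gy deltas
  and P1–P99 point-dose-difference statistics per technique × scenario.

## Worked example

```r
library(expanderRobust)
cfg <- defaultRunConfig(seed = 1L, techniques = "tangential")
rep <- runPipeline(cfg)
rep
```

```
RobustnessReport
  technique errorClass       scenario dV100Roi_pct dV20Lung_pct dV5Heart_pct
 tangential       none      reference    0.0000000    0.0000000     0.000000
 tangential        IPE      daily-IPE    0.0000000    0.0000000     0.000000
 tangential        PRE      daily-PRE    0.0000000    0.5088326     1.078216
 tangential        IPE systematic-IPE   -8.2125604    0.0000000     0.000000
 tangential        PRE systematic-PRE  -22.9468599   -8.9381720   -11.019737
 tangential       none       override    0.4830918    0.0000000     0.000000
  meanDiff_pct  iqrDiff_pct   p1Diff_pct   p99Diff_pct
  0.0000000000 0.0000000000   0.00000000  0.000000e+00
  0.0006904305 0.0002970269  -0.02686655  5.813129e-02
 -0.0030752547 0.0207008550  -0.02566288  1.822671e-02
 -0.4935219521 0.3530365518  -4.79669167 -7.820106e-06
 -1.0478912528 1.7581466388 -10.14012206  1.061025e+00
  0.0490230696 0.0040168583   0.00000000  8.701259e-01
```

Reading the rows: daily-variable errors barely move the cumulative dose
(V100%Rx of the ROI unchanged, point-dose IQR well under 1% of the 50 Gy
prescription) because 25 independent small shifts largely average out. A
persistent systematic error is far more damaging: the −17 mm lateral port
shift (systematic-IPE) drops ROI coverage by 8 percentage points, and the
same shift applied as a whole-patient registration error (systematic-PRE)
costs 23 points. Overriding the metal port with tissue density
(`override`) slightly *increases* the apparent ROI dose — ignoring the port
at planning time overestimates coverage. Columns `dV20Lung_pct` and
`dV5Heart_pct` report the same deltas for the slice-restricted ipsilateral
lung and heart.

Run all three techniques (`defaultRunConfig(seed = 1L)`) to compare their
robustness: the conformal arc and helical-like plans lose the most coverage
under registration errors, while the tangents show the widest spread of ROI
point-dose differences when the port itself migrates through their fixed
beam paths.

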