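# rangewedge

Measurement-based evaluation of proton range uncertainty on CT and
cone-beam CT (CBCT), with a daily dose-verification workflow.

## What problem this solves

Proton dose calculation converts image Hounsfield units (HU) to mass
density and then to relative stopping power (RSP); any calibration error
becomes a *range* error — the Bragg peak stops at the wrong depth. CBCT,
acquired daily at the treatment machine, has inferior HU fidelity to
helical CT, so the question for anyone wanting CBCT-based daily dose
checks is: **how large is the range error of a CBCT-based calculation,
measured against a physical baseline rather than against CT?**

The method implemented here answers it with a wedge trick. A single
anterior–posterior beam delivers a homogeneous dose (200 cGy) to a
wedge-shaped target whose distal surface slopes linearly across the
field, so the distal falloff sweeps across a 2D detector plane behind
the phantom. The measured plane is gamma-compared (3%/3 mm) against
calculated planes extracted every 1 mm of depth; the depth whose plane
matches best is where the measurement *actually* was, in the
calculation's own depth scale. The offset from the physical detector
depth, normalized by the water-equivalent path length (WEPL) to the
detector,

```
epsilon = 100 * (d_physical - d_best) / WEPL    [%]
```

is the percentage range error of the whole imaging-to-dose chain
(positive when the calculation's stopping power is too high). The same
forward chain applied to serial CBCTs, with the planned beam held
fixed, gives the daily verification workflow: recalculate, compute DVH
metrics (target V100%, organ-at-risk doses), trend, flag coverage loss.

Audience: medical-physics researchers and tool builders working on
CBCT-based proton dose verification, adaptive-therapy QA, or range
uncertainty methodology, who need a fully synthetic, reproducible test
bed (the package ships an analytic pencil-beam dose engine, digital
head/thorax phantoms, a CBCT distortion model, and a detector
simulator in place of the commercial TPS and physical hardware).

## Worked example

Build the default head phantom, optimize the wedge plan, simulate a
noisy detector measurement, then recalculate with a deliberate +1%
stopping-power error and recover it:

```r
library(rangewedge)

spec    <- phantom_spec("head")
phantom <- make_phantom(spec)

ct_table <- default_ct_table()
rsp_tab  <- default_rsp_table()
density  <- density_from_hu(phantom$ct, ct_table)
density  <- apply_density_override(density, phantom$base, 1.00)  # solid-water base
rsp      <- rsp_from_density(density, rsp_tab)

beam <- build_wedge_beam(phantom$wedge, rsp, prescription = 200)
dose <- attr(beam, "plan_dose")
measurement <- simulate_measurement(dose, depth = spec$detector_depth,
                                    noise = 0.01, seed = 1)

rsp_bad <- rsp; rsp_bad$values <- rsp$values * 1.01   # +1% RSP error
dose_bad <- compute_beam_dose(beam, rsp_bad)
sweep <- sweep_depths(measurement, dose_bad, window = 10, step = 1)
best  <- best_match(sweep)
wepl  <- wepl_to_detector(rsp_bad, beam, as.numeric(best),
                          dose = dose_bad, lattice = measurement)
percent_range_error(best, spec$detector_depth, wepl)
```

Output from this session:

```
plan: 3529 spots, 99.2% of target within +/-5% of 200 cGy
<planar_dose> 27x27 @ depth 118.00 mm (axis 2), pitch 10x10 mm, max 204 cGy
<range_sweep_result> 21 depths in [108.0, 128.0] mm; peak 100.00% at 117.0 mm
  refined best depth 117.048 mm; range error +0.993% of 96.0 mm WEPL
```

Reading it: the plan met its homogeneity contract (99.2% of wedge
voxels within ±5% of 200 cGy); the measurement sits physically at
118 mm, but with the +1% RSP error the calculation's best-matching
plane is at 117.05 mm — about 1% of the 96 mm effective WEPL — so the
injected error is recovered as +0.99%. The higher-level
`evaluate_range_uncertainty()` runs this whole chain (image → density
→ RSP → dose → sweep → error) in one call, and `verify_daily()` /
`batch_report()` provide the fraction-by-fraction DVH monitoring.

A command-line interface covering simulation, gamma comparison, range
evaluation, daily verification and trending is installed at
`inst/cli/rangewedge` (see `?rw_cli`).

## Package layout

- `R/grids.R`, `R/contours.R`, `R/dicom.R`, `R/measurement.R` —
  geometry-aware containers, rigid resampling, contour rasterization,
  minimal DICOM codec (CT series, RT Dose), detector-plane ASCII.
- `R/hu_density.R` — HU–density tables, group-based CBCT calibration,
  density→RSP conversion, solid-water overrides.
- `R/bragg.R`, `R/phantom.R`, `R/plan.R` — analytic Bragg model, WEPL
  ray tracing, spot dose engine (Rcpp kernel), digital phantoms, CBCT
  distortion, detector simulation, wedge-plan optimizer.
- `R/gamma.R` — 2D gamma index with brute-force oracle.
- `R/range_eval.R` — plane extraction, depth sweep, best-match
  refinement, percentage range error.
- `R/monitor.R` — DVH, daily verification, trend reports.
- `vignettes/range-uncertainty-methods.Rmd` — models, assumptions,
  parameter choices, and limitations.
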