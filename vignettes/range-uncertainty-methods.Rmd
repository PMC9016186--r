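---
title: "Measurement-based proton range uncertainty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement-based proton range uncertainty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Proton dose distributions stop: the Bragg peak's distal falloff is the
steepest gradient in radiotherapy, and its position in the patient is
governed by the integral of relative stopping power (RSP) along the beam
path -- the water-equivalent path length (WEPL).  Dose calculated on a
daily cone-beam CT (CBCT) therefore inherits any error in the CBCT's
Hounsfield-unit (HU) to density calibration as a *range* error.  This
package implements a measurement-anchored way to quantify that error:

1. A single anterior-posterior beam delivers a homogeneous dose to a
   wedge-shaped target whose distal surface slopes linearly across the
   field, so the distal dose gradient sweeps across a 2D detector plane
   placed behind the phantom in a solid-water base.
2. The 2D measured plane is compared against 2D planes extracted from
   the calculated 3D dose at 1 mm depth spacing using the 2D gamma
   index (3%/3 mm).  Because the wedge converts depth into a lateral
   edge position, a range error shifts the measured pattern along the
   depth axis only; the candidate depth with the highest passing rate
   identifies the depth the measurement actually corresponds to.
3. The offset between best-matching and physical detector depth,
   normalized by the WEPL to the detector, is the percentage range
   error of the calculation chain (HU to density to stopping power).

The same forward-calculation chain, applied to serial CBCTs with the
planned beam held fixed, gives the daily dose-verification workflow:
recalculate, compute DVH metrics (target V100%, organ-at-risk mean/max
dose), trend them across fractions, and flag coverage loss.

Because the physical detector, the commercial treatment planning
system, and the patient images behind the original study are not
distributable, the package carries a synthetic stand-in for each: an
analytic pencil-beam dose engine, digital head/thorax phantoms, a
CBCT distortion model, and a detector simulator.  These are first-class
tested code, and every quantitative claim in the test suite is made
against them.

## Dose engine

The pristine depth dose is a two-piece analytic Bragg curve in
water-equivalent depth $w$ with nominal range $R$:

$$D(w) = \begin{cases} p + (1-p)\,e^{-(w-R)^2/2\sigma_p^2}, & w \le R \\
e^{-(w-R)^2/2\sigma_d^2}, & w > R \end{cases}$$

with entrance plateau $p = 0.35$, proximal shoulder
$\sigma_p = 6$ mm and distal falloff $\sigma_d = 3$ mm by default.  It
is continuous with $D(R) = 1$, and its distal 50% point sits at
$R + \sigma_d\sqrt{2\ln 2}$ -- the closed forms the tests pin down.
This replaces a Monte Carlo engine deliberately: the evaluation target
is range *consistency*, which needs a controllable, exactly known
distal gradient, not spectrum realism.  Nuclear halo, range straggling
growth and multiple-Coulomb-scattering growth of the lateral spot with
depth are omitted; each spot keeps a constant lateral Gaussian width
(default $\sigma_{lat} = 4$ mm).

WEPL is accumulated along grid-aligned rays with the midpoint rule
($W_k = \sum_{j\le k} \mathrm{RSP}_j\Delta - \mathrm{RSP}_k\Delta/2$),
so a voxel's $W$ is the water-equivalent depth of its center.  The key
engine invariant, exercised in the acceptance tests, is the range
scaling law: multiplying all RSP values by $k$ moves every column's
distal-50% geometric depth by $1/k$ to within half a voxel.

Beam axis is restricted to a grid axis (the phantom study's geometry is
a single anterior-posterior field); general-angle ray tracing is out of
scope for verifiability.

## Calibration chain

HU to mass density is a piecewise-linear anchor table per modality,
clamped outside its anchors (no extrapolation: extreme HU cannot
produce unphysical densities).  The CBCT table is fitted by the
patient-group method: volumes of interest of nearly homogeneous
material (air, lung, soft tissue, bone, density-phantom inserts)
provide (mean CBCT HU, density) pairs, densities taken from known
insert values or from the CT reference table at the VOI's CT HU.  Noisy
VOIs can invert density ordering; a weighted pool-adjacent-violators
pass restores monotonicity with a warning rather than rejecting the
calibration.  Density to RSP is a single piecewise-linear table
(anchors at air, lung, adipose, water, bone; RSP(1 g/cm³) = 1 by
construction), collapsing the composition and mean-ionization-energy
interpolation of clinical engines; that simplification is acceptable
here because both the "truth" and the recalculation use the same map,
and the quantity under test is the consistency of ranges, not absolute
stopping-power theory.  The solid-water base is overridden to exactly
1.00 g/cm³ in every calculation, mirroring clinical practice of
overriding known devices.

## Digital phantoms

The head is a soft-tissue ellipsoid (1.04 g/cm³) with a 4 mm bone
shell (1.55 g/cm³) resting on a 30 mm solid-water slab; the thorax
adds two lung ellipsoids (0.26 g/cm³) on a 2 mm grid (half resolution
purely for runtime).  The wedge target's distal surface runs linearly
from 104 mm to 127.7 mm depth across the field (slope 0.3 mm/mm) and
brackets the detector plane at 118 mm inside the slab, so the distal
gradient crosses the detector -- the geometric trick the whole method
rests on.  Defaults were chosen once so that the wedge gradient spans
the detector with the field's lateral edge comfortably inside the
27x27, 10 mm pitch detector; they are configuration, not a claim about
the original phantoms' dimensions.

Material interfaces are anti-aliased by 2x2x2 subvoxel supersampling,
mimicking CT partial-volume averaging.  This matters more than it
looks: with binary voxel classification, the oblique bone shell
aliases into a column-parity WEPL ripple of almost one voxel
(neighboring columns crossing 8 vs 10 shell voxels), which imprints a
+/-2 mm sawtooth on every distal dose surface.  Real anatomy does not
do this, and neither does real CT.

CT HU is synthesized by inverting the CT table at each voxel's density
(so noise-free conversion recovers the truth exactly), with optional
seeded Gaussian HU noise.  CBCT distortion is applied in image domain:
per-material-class affine HU maps, an optional radial cupping term, and
seeded HU noise.  What the generator does *not* emulate: scatter and
beam-hardening structure beyond cupping, motion artifacts, truncation,
metal.  A green calibration-closure test therefore establishes that
*the calibration pipeline* is unbiased under class-wise HU distortion
with noise -- not that any particular scanner's CBCT is this benign.

The detector simulator samples the 3D dose by trilinear interpolation
on the chamber lattice (27x27 at 10 mm pitch by default -- the pitch
of common 2D chamber arrays; the study does not state its detector
model) and applies multiplicative Gaussian noise, seeded.

## Spot-weight optimization

The planner lays spots on a 5 mm lateral lattice covering the target's
beam's-eye-view footprint plus one ring (so the optimizer can sharpen
the field edge), stacks energy layers per lattice position from the
local distal WEPL inflated by the 3.5% range margin down to the
proximal surface in $\sigma_d$ steps, and solves nonnegative least
squares against a uniform prescription over (a deterministic sample
of) target voxels with L-BFGS-B under a zero lower bound.  The plan
contract -- at least 95% of target voxels within +/-5% of 200 cGy --
is checked on the full recomputed dose; a failing plan is returned
with a warning and flag, never silently.  The default head plan
reaches about 99%.

Two scales are offered: the raw least-squares scale centers the target
dose on the prescription (maximal homogeneity margin; used for the
plan-contract and range-evaluation work), while `normalize = "D98"`
rescales weights so 98% of the target receives the prescription -- the
coverage convention under which V100% is a meaningful monitoring
metric.  A plan centered exactly on the prescription necessarily has
V100% near 50%, which is why the monitoring workflow uses the D98
scale.

## Gamma comparison

The 2D gamma index uses global normalization to the maximum reference
dose (the plane-array QA convention; the study does not state its
normalization), a 10% low-dose threshold (excluded points are not
counted in the passing rate), a search disk of 3 distance criteria,
and bilinear interpolation of the evaluated plane on a 0.3 mm
($\Delta d/10$) offset lattice, bounding the discretization error of
$\gamma$ at roughly 0.1.  Points whose disk leaves the evaluated plane
search the truncated disk and are flagged.  A point passes at
$\gamma \le 1 + 10^{-9}$; the epsilon keeps exact boundary cases (a
uniform 3% dose offset gives $\gamma = 1$ analytically) from failing
on floating-point rounding.  The measurement is always the reference:
gamma is not symmetric, and the test suite documents an asymmetric
case.  A brute-force implementation with an independently written
interpolation enumerates the identical candidate set with no pruning;
the fast path must agree with it to $10^{-6}$ per point.

## Range-error estimation

Candidate planes are extracted at 1 mm spacing in a +/-10 mm window
around the physical detector depth and gamma-scored against the
measurement; no lateral re-registration is ever applied, enforcing the
working assumption that calibration errors shift the pattern only
along the range direction (violations surface as low peak passing
rates, not silent shifts).  The best depth is the passing-rate argmax
refined by a parabolic fit through the peak and its neighbors;
plateaus of equal maxima return the plateau midpoint with a
low-confidence flag, and an all-equal sweep is an error (no gradient,
no range information).

The percentage range error is
$\varepsilon = 100\,(d_{phys} - d_{best})/W$: positive when the
calculation's stopping power is too high, so that a uniform +f% RSP
error is recovered as $\varepsilon \approx +f$.  The denominator $W$
deserves care, and the design here departs from the obvious choice.
Under a curved entry surface the WEPL to the detector varies by tens
of percent across the field, and the rigid best-match depth is
effectively a weighted average of the per-column ideal shifts.  Using
the central-axis WEPL (the largest in the field) as denominator
therefore biases $|\varepsilon|$ low -- measured as a recovery slope
of 0.88 instead of 1 on the default head phantom.  The package instead
uses the *depth-sensitivity-weighted mean WEPL*: each detector lattice
point is weighted by the squared depth-derivative of the calculated
dose at the matched plane.  This is the WEPL scale consistent with a
weighted-least-squares depth estimator (Gauss-Newton weighting), it
reduces to the central-axis value for laterally uniform phantoms, and
it is evaluated at the matched plane because that plane's pattern is
the one the measurement was matched to.  With it, injected RSP
scalings of -2% to +2% are recovered with max error ~0.13% and
regression slope within 1% of unity, with and without 1% measurement
noise.  The central-axis definition remains available
(`wepl_to_detector(..., method = "central_axis")`).

## Monitoring workflow

Daily verification resamples the daily image rigidly into the planning
frame, recalculates the fixed beam (no re-optimization), computes DVH
metrics, and compares them to thresholds (default: flag target V100%
below 95%, the neighborhood of the study's worst single-plan
coverage).  DVHs are cumulative on uniform 1 cGy bins with V(0) = 100%
exactly; Vx% metrics interpolate linearly within the bin containing
the level, giving sub-bin resolution.  The full beam corridor (lateral
spot extent padded by 3 sigma, entire depth) must lie inside the daily
image's field of view -- truncation is a hard error, since a clipped
beam path silently corrupts the recalculated range.  Breath-hold
variability is emulated as an uncorrected rigid superior-inferior
translation of the daily anatomy; on the thorax phantom an 8 mm shift
moves lung tissue through the beam path, changes the WEPL to the
target, and demonstrably collapses V100% (98% to ~81% on the default
configuration).

## Numerical choices and degenerate inputs

* Trilinear/bilinear interpolation everywhere; no splines, for
  reproducibility.
* Resampling fill values are quantity-dependent (air HU -1000, air
  density, 0 dose/RSP).
* Contour rasterization uses the even-odd rule with points exactly on
  an edge counted inside, so a square with vertices on voxel centers
  fills the inclusive lattice; multiple polygons on one slice combine
  by XOR (disjoint shapes union, nested shapes carve holes).
* DICOM support is a minimal self-consistent explicit-VR-little-endian
  codec (CT series and multi-frame RT Dose; no sequences, no
  compression), because no DICOM package exists in the supported
  environment; dose pixels are 32-bit with a `DoseGridScaling` of
  $\max D / (2^{31}-1)$, so round-trip error is below
  $\max D / 2^{31}$ per voxel.
* All stochastic components (phantom noise, CBCT noise, detector
  noise) restore the caller's RNG state and are bit-reproducible under
  their seeds.

## Known limitations

The dose engine's analytic peak has no nuclear buildup or halo, so
absolute entrance-region doses are stylized.  Only grid-aligned beams
are supported.  The range estimator assumes a single rigid depth shift;
differential (per-column) range errors are reported only through a
depressed peak passing rate.  The synthetic CBCT distortion is
class-wise affine plus cupping and noise -- adequate for testing the
calibration *pipeline*, not a scanner model.  Range errors smaller than
about 0.1% of the WEPL are below the refinement resolution of the 1 mm
sweep with parabolic refinement on a 10 mm pitch detector.
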