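---
title: "Propagating lumen reconstruction errors into wall shear stress metrics"
author: "wssphantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating lumen reconstruction errors into wall shear stress metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssphantom)
```

## The problem

Wall shear stress (WSS) — the tangential viscous traction that flowing
blood exerts on the vessel wall — is a key hemodynamic correlate of
atherosclerosis: regions of low (< 0.5 Pa) and oscillating WSS near
coronary bifurcations preferentially develop plaque. WSS cannot be measured
in vivo; it is computed from a reconstructed lumen geometry. When that
geometry comes from segmentations of bi-plane angiograms, small
reader-dependent reconstruction errors (of the order of the imaging
resolution, ~0.1 mm) propagate into the computed WSS. Because developed-flow
WSS scales with the inverse cube of the lumen radius, even sub-resolution
radius errors translate into tens of percent of WSS error.

`wssphantom` implements the phantom-study methodology for quantifying this
propagation in a mildly diseased coronary bifurcation: a ground-truth
parametric phantom, simulated reader reconstructions, a surrogate flow
model, the standard WSS metrics (steady WSS, TAWSS, OSI, low-WSS area and
its Dice similarity), a 2D surface unwrapping for position-resolved
comparison, and a margin-based equivalence analysis.

## The phantom

The geometric ground truth is a single region of interest: a straight,
planar main branch with three regions — a constant-radius proximal segment,
a concentric stenosis, and a constant-radius distal segment — plus one side
branch. The stenosis is a C1 double half-cosine narrowing whose throat
radius realizes the configured area stenosis
$AS = 100\,(1 - (a_\text{throat}/a_\text{prox})^2)$, 60% by default
(mildly diseased). Defaults: proximal radius 1.25 mm (a representative
coronary radius, the same nominal value the analytic error model uses — the
physical phantoms' absolute radii are not published), stenosis length
7.5 mm centered at 9 mm, total length 25 mm, side branch of radius 0.85 mm
at 16 mm under 60 degrees. The stenosis sits proximal to the side branch,
the predominant configuration in this kind of phantom set.

Two geometry choices deserve comment:

* **Murray-consistent distal radius.** The default distal radius is
  $(a_\text{prox}^3 - a_\text{side}^3)^{1/3} \approx 1.10$ mm. The package
  splits outflow between the distal main branch and the side branch by the
  diameter-cube law, and a cube-law-consistent geometry keeps the WSS
  homeostatic (~1 Pa) on both sides of the bifurcation — also how
  validation phantoms of coronary bifurcations are dimensioned. An
  equal-diameter default would make the distal WSS systematically lower
  than proximal and artificially insensitive to reconstruction errors.
* **Mesh construction.** The surface is a structured swept tube; the
  side branch is extruded from the rim of the ostium hole so the join is
  watertight and the mesh has exactly three boundary rims (inlet, main
  outlet, side outlet). Generation is fully deterministic.

Lengths are in mm, stresses in Pa, time in s.

## Simulated readers

Reader segmentation errors are emulated as a seeded Gaussian random field
on the (arclength, circumference) parameterization of the main-branch wall,
smoothed to a correlation length (default 2 mm, so errors look like smooth
hand-contour deviations rather than pixel noise) with kernels normalized to
keep the field variance stationary along the vessel. The field is rescaled
so that the realized mean absolute per-ring radius error
$\langle|\delta r|\rangle$ equals the requested amplitude exactly —
per-ring, because reconstruction accuracy is conventionally reported on
radius profiles measured per cross-section. The default amplitude is
0.08 mm, the reported scale of reader errors (< 0.10 mm). A configurable
angular offset of the side branch (default ±2 degrees for the two default
readers) emulates the branch-angle component of reconstruction error.
Excursions that would close the lumen are floored at 20% of the local
radius: a reconstruction of a contrast-filled, patent lumen never closes
it. Identical seeds reproduce reconstructions bit for bit.

## The surrogate flow model

Solving Navier–Stokes is out of scope; the surrogate produces WSS vector
fields with the *structure* CFD produces in these geometries, so that the
downstream metrics are exercised realistically:

* **Quasi-steady developed-flow magnitude.** Per face,
  $\tau = q_\text{local}(\beta+2)\mu_\text{eff}/(\pi a^3)$ with
  $\beta = 2$ (parabolic profile; the Womersley number at these conditions
  is ~2, reported as a diagnostic of the quasi-steady assumption). The
  local wall shear rate $\dot\gamma = q(\beta+2)/(\pi a^3)$ is independent
  of viscosity, so the Carreau effective viscosity
  $\mu_\text{eff} = \mu(\dot\gamma)$ is exact in a single pass (the
  standard blood parameters: 0.056 / 0.00345 Pa s, 3.313 s, 0.3568,
  density 1060 kg/m³).
* **Flow.** The inlet flow follows from a parabolic profile with a peak
  velocity of 0.15 m/s at the proximal radius (0.368 ml/s). The pulsatile
  waveform is a two-lobe, diastole-dominant parametric curve over a 0.8 s
  cycle in 100 steps, rescaled so its mean matches the steady flow exactly.
  Outflow splits by the diameter-cube law.
* **Post-stenotic recirculation.** Distal of the stenosis exit a crescent
  of retrograde WSS (angular extent 200°, centered on the wall opposite
  the side branch) reverses the direction and scales the magnitude by
  0.35, tapering linearly to zero at the reattachment line
  $L_r(t) = 0.088\, Re_\text{jet}(t)\, (a_\text{dist}-a_\text{throat})$.
  The coefficient and the step-height scaling are the standard laminar
  sudden-expansion (backward-facing-step) correlation. Scaling with
  $a_\text{throat}$ instead would make $Re_\text{jet}\,a_\text{throat}$
  independent of the throat radius (since $Re \propto 1/a$) and the
  recirculation zone insensitive to exactly the reconstruction errors whose
  effect the model exists to express; the step height restores that
  sensitivity and vanishes without a stenosis. As the flow pulses, the
  reattachment line sweeps axially, producing the characteristic band of
  elevated OSI (up to ~0.5) distal of the stenosis.

This is a deliberately simple structural model, not CFD: it has no jet
deflection, no secondary flows, no wall mechanics, and its recirculation is
imposed rather than solved. What passing tests show is that the *metrics
and statistics* downstream behave correctly and that error propagation has
the right structure (cubic radius sensitivity, jet-zone sensitivity); they
do not validate absolute WSS in any real artery.

## Metrics

* `tawss()` — time-averaged $|\vec\tau|$ over one period, trapezoidal on
  the uniform periodic grid (which reduces to the sample mean).
* `osi()` — $\tfrac12(1 - |\int\vec\tau\,dt| / \int|\vec\tau|\,dt)$,
  clipped to $[0, 0.5]$; all-zero faces get OSI 0 (no oscillation), not NaN.
* `low_wss_mask()` — strict `value < threshold` (default 0.5 Pa), so area
  fractions are bit-reproducible.
* `similarity_index()` — area-weighted Dice overlap
  $2|A\cap B|/(|A|+|B|)$; when both masks are empty the SI is defined as 1
  (perfect agreement about "nothing") and flagged. Across two different
  geometries, masks are compared on the common clipped 2D bin grid
  (`similarity_index_map()`), since no face-to-face correspondence exists.
  The SI is reported for steady WSS; low-TAWSS areas are typically small,
  so their SI is volatile and should be read with care.

## 2D unwrapping

`build_bin_grid()` unwraps the main-branch wall onto axial rows of 0.45 mm
by 16 angular bins of 22.5°. Faces are assigned by centroid (no area
splitting — the assignment error vanishes as the mesh resolution becomes
much smaller than the bins); bin means are area-weighted (the natural
weighting for surface aggregates; a vertex-sampled alternative differs only
at mesh scale). The circumferential origin is the direction from the
centerline to the side-branch ostium, parallel-transported along the
vessel, which makes maps of the phantom and its reconstructions directly
comparable. The side branch itself is not mapped; bins inside the ostium
are invalid. `clip_align()` registers two maps on the axial position of the
minimum radius — searched within the stenosis-labeled rows, so extreme
perturbations cannot drag the registration outside the stenosis — and crops
both to identical shape and validity. Region labels (proximal / stenosis /
distal) are defined on the ground-truth phantom profile, as the regions are
defined by where the phantom diameter is constant.

## Equivalence statistics

The analytic error model turns the resolution limit into a margin: with the
wall at $a' = a \pm \delta$, the relative WSS error is
$(1 - (a/a')^3) \cdot 100\%$ — for $a = 1.25$ mm and $\delta = 0.1$ mm,
the range is −28% to +21% (the cube makes underestimation worse). A
conservative ±25% at the nominal ~1 Pa proximal WSS gives the 0.25 Pa
margin for WSS and TAWSS; the same fraction at the nominal 0.2 peak
directional-mean OSI gives 0.05 for OSI.

`equivalence_map()` classifies each position of two clip-aligned maps or
directional-mean profiles as equivalent when $|A - B| <$ margin (strict,
per the margin's definition) and reports the area-weighted percentage of
equivalent positions per region. The cited noninferiority test is realized
as two one-sided t-tests (TOST, `tost_region()`) at $\alpha = 0.05$ per
region on the pooled directional-mean differences; the reference for the
test gives no formula, so TOST — the standard construction for
margin-based equivalence — is used and labeled as such. Both the
per-position classification and the per-region test are emitted, since the
unit of testing is ambiguous in the source methodology. No multiple-testing
correction is applied (none is applied in the source either). Zero-variance
difference vectors are decided exactly on the mean.

## The full study

`run_study()` chains everything: phantom → per-reader perturbation →
steady and pulsatile surrogate fields on every geometry → metrics → 2D
maps → SI, per-region mean absolute differences, and per-region percentage
of equivalence for steady WSS / TAWSS / OSI in both averaging directions →
fixed-format CSV/JSON tables (byte-identical across reruns of the same
configuration), PLY meshes, PNG heat maps with a saturated color scale
(cap 2 Pa), and a manifest with all seeds. Defaults: two simulated readers
(seeds 1 and 2), mesh resolution 0.25 mm, 100 time steps.

Problem sizes were chosen so a full default study runs in seconds on one
CPU (meshes of ~10⁴ faces; the test suite uses 0.3 mm meshes and reduced
step counts). The degradation analysis in the test suite uses amplitudes
{0.02, 0.08, 0.2} mm × 10 seeds with steady fields.

A note on statistical power: the proximal segment spans only ~2.5
correlation lengths of the reader-error field, so its per-seed equivalence
percentage is highly variable. The degradation test therefore asserts the
robust orderings — stenosis below proximal, and the pooled post-stenotic
vessel below proximal — rather than every pairwise contrast at n = 10
seeds. In expectation (verified on larger seed sets during development) the
full ordering proximal > distal > stenosis holds.

## Numerical and I/O conventions

* Strict thresholds; trapezoidal-on-periodic-grid integration; 1e-6 mm/mm
  slope tolerance for region detection on generated profiles (configurable
  for measured ones).
* All text artifacts use 9-significant-digit fixed formatting; mesh I/O is
  ASCII PLY/OBJ (STL read-only) — ASCII round-trips losslessly at that
  precision and keeps every artifact diffable.
* Degenerate cases: constant profile → empty stenosis region (flagged);
  both-empty masks → SI 1 (flagged); all-zero WSS → OSI 0; TOST with
  zero variance → exact decision on the mean.

## Known limitations

* The surrogate is not CFD; absolute WSS values in the stenotic jet and
  recirculation zone are structural, not quantitative.
* One ROI (one stenosis, one side branch), straight planar centerline;
  curved or multi-branch trees are out of scope, as is reconstruction from
  actual 2D projections.
* The reader-error model is a stationary random field; real reader errors
  can be spatially biased (e.g., consistently over-segmenting the
  stenosis), which is representable only by per-region amplitude choices.
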