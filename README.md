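# wssphantom

Quantify how small lumen-reconstruction errors propagate into wall shear
stress (WSS) metrics in mildly diseased coronary bifurcations.

WSS — the tangential viscous traction of blood on the vessel wall — marks
arterial sites at risk of atherosclerosis: low (< 0.5 Pa) and oscillating
WSS near bifurcations predicts plaque progression. WSS is computed, not
measured: a lumen geometry is reconstructed from imaging (e.g. bi-plane
angiography segmented by human readers) and a flow computation yields
τ⃗ on the wall. Because developed-flow WSS scales as

    τ = q (β + 2) μ / (π a³)

a radius error δ of the order of the imaging resolution changes the
computed WSS by (1 − (a/a′)³)·100 % with a′ = a ± δ — for a 1.25 mm
coronary radius and δ = 0.1 mm, between −28 % and +21 %. This package
implements the complete phantom-style experiment for studying that
propagation, for researchers in computational hemodynamics and
image-based cardiovascular modeling:

* **geometry** — parametric ground-truth bifurcation phantoms (three-region
  main branch with a concentric area stenosis + one side branch) as
  triangulated surface meshes; mean Hausdorff distance; radius-profile and
  region analysis;
* **simulated readers** — seeded, smoothly correlated radial error fields
  (default mean |δr| = 0.08 mm) plus side-branch angle offsets emulating
  reader segmentation variability;
* **surrogate hemodynamics** — an analytic quasi-steady WSS vector field
  (Poiseuille-type magnitude with Carreau viscosity, diameter-cube outflow
  split, pulsatile 0.8 s coronary waveform, and a post-stenotic retrograde
  crescent whose reattachment line follows the laminar sudden-expansion
  correlation) standing in for a CFD solver;
* **metrics** — steady WSS, TAWSS, OSI = ½(1 − |∫τ⃗dt|/∫|τ⃗|dt), low-WSS
  (< 0.5 Pa) areas and their Dice similarity index SI = 2|A∩B|/(|A|+|B|);
* **2D mapping** — unwrapping onto the standard 0.45 mm × 22.5° bin grid,
  circumferential/axial directional means per vessel region, throat-based
  map registration;
* **equivalence statistics** — resolution-based margins (0.25 Pa for
  WSS/TAWSS, 0.05 for OSI), per-position equivalence with per-region
  percentages, and a TOST noninferiority test at α = 0.05.

## Worked example

```r
library(wssphantom)

spec <- bifurcation_spec()
spec
#> Bifurcation phantom spec (single ROI)
#>   main branch : length 25 mm, a_prox 1.25 mm, a_dist 1.1022 mm
#>   stenosis    : 60% area, center 9 mm, length 7.5 mm (proximal-to-branch)
#>   side branch : radius 0.85 mm, angle 60 deg, ostium at 16 mm

area_stenosis_percent(build_radius_profile(spec))
#> [1] 60

analytic_relative_error(1.25, 0.1, rounded = TRUE)
#> eps_min eps_max
#>     -28      21
derive_margin(1, 0.25);  derive_margin(0.2, 0.25)
#> [1] 0.25
#> [1] 0.05

res <- run_study(study_config(resolution = 0.3, n_steps = 50))
res$si_table[, 1:3]
#>     model si_steady si_tawss
#> 1 reader1     0.709    0.692
#> 2 reader2     0.952    1.000
subset(res$equivalence_table, direction == "circumferential")
#>      model metric       direction margin proximal stenosis distal
#> 1  reader1    wss circumferential   0.25     73.6     21.1   46.7
#> 3  reader1  tawss circumferential   0.25     73.6     21.1   65.9
#> 5  reader1    osi circumferential   0.05    100.0    100.0   80.4
#> 7  reader2    wss circumferential   0.25    100.0     35.6  100.0
#> 9  reader2  tawss circumferential   0.25    100.0     35.6  100.0
#> 11 reader2    osi circumferential   0.05    100.0    100.0   89.4
```

Reading the output: the two simulated readers (mean |δr| ≈ 0.08 mm,
Hausdorff ≈ 0.09 mm from `res$geometry_table`) still agree with the
phantom's low-WSS region to Dice 0.7–0.95, and the proximal vessel is
largely clinically equivalent (|ΔWSS| < 0.25 Pa), while the stenosis —
where WSS is amplified by the inverse-cube law — is mostly *not*
equivalent, and the distal region (jet/recirculation zone) sits in
between. OSI differences stay mostly inside the 0.05 margin except around
the moving reattachment zone. `run_study(cfg, out_dir = "...")` writes all
tables (CSV/JSON), 2D maps (CSV + PNG), meshes (PLY) and a seed manifest;
reruns are byte-identical.

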