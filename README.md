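# csfhydro

Quantifies spinal intrathecal cerebrospinal-fluid (CSF) **geometry and
hydrodynamics** from MRI: segmented anatomic label volumes (NIfTI) plus
cardiac-gated phase-contrast MRI (PC-MRI) per-pixel velocity exports go in;
axial geometric profiles, offset-corrected flow waveforms, a smooth
spatio-temporal flow surface `Q(z, t)`, pulse wave velocity (PWV),
per-millimetre hydrodynamic features (stroke volume, peak flow rates, mean
velocities, Reynolds and Womersley numbers) and cohort / test–retest
summaries come out.

CSF in the subarachnoid space (SAS) — the annulus between spinal cord and
dura — oscillates with every heartbeat.  Its geometry (areas, perimeters,
hydraulic diameter `D_h = 4A/P`) and hydrodynamics (dimensionless `Re` and
Womersley `α`, stroke volume, PWV as a surrogate for compliance) are the
quantities intrathecal drug-delivery and disease models need.  Conventions:
`z` in mm caudal of the foramen magnum (FM), caudal (systolic) flow
negative, units mm / mm² / ml / s / cm/s / ml/s fixed at the boundary.

A **digital-phantom generator** (annular geometry + travelling-wave
velocity exports + analytic ground-truth manifest, in exactly the file
formats the readers consume) makes the whole pipeline testable without
scanner data.

## Worked example

Generate a phantom study on disk (prescribed PWV 1.2 m/s, 5% velocity
noise), then analyse it exactly as you would real data:

```r
library(csfhydro)

dir  <- tempfile()
cfg  <- phantom_config(pwv = 1.2, noise_sd = 0.05, seed = 42)
paths <- write_phantom(cfg, dir)       # NIfTI labels + velocity CSVs + truth

## geometry: label volume -> axial profiles -> whole-spine totals
seg  <- read_segmentation(paths$segmentation)
prof <- slice_profiles(seg)            # z, A_c, A_d, A_sas, P_*, D_h per mm
geom_totals(prof)
#> <global_geometry> SA_c 22.34 + SA_d 55.55 = SA_sas 77.89 cm^2; V_d 9.04 - V_c 2.33 = V_sas 6.71 ml; L_sas 300.0 mm

## flow: pixel velocities -> offset-corrected waveforms -> Q(z, t) surface
rois  <- lapply(paths$velocity, read_velocity_csv)
waves <- lapply(rois, function(r) offset_correct(waveform_from_pixels(r))$waveform)
stf   <- fit_spatiotemporal(waves)
stf
#> <stf_surface> 238 z-levels (0..237 mm) x 24 phases, T = 0.550 s

## pulse wave velocity from peak-systole arrival at the acquired slices
pulse_wave_velocity(peak_arrival(stf, at = stf$source_z))
#> <pulse_wave> PWV = 1.167 m/s (slope 0.000857 s/mm, R^2 0.999, n = 6)

## per-level hydrodynamics from the surface + local geometry
hy <- hydrodynamic_profile(stf, prof)
round(subset(hy, z %in% c(5, 25, 70)), 3)
#>     z  Q_sys Q_dia   Q_a    SV  U_sys U_dia     Re  alpha
#> 6   5 -0.315 0.182 0.496 0.056 -0.440 0.255 38.269 12.228
#> 26 25 -0.541 0.325 0.867 0.101 -0.963 0.578 66.112  9.662
#> 71 70 -0.450 0.277 0.727 0.085 -5.709 3.518 80.609  1.986
```

The recovered PWV (1.167 m/s) sits within 3% of the prescribed 1.2 m/s at
this noise level; the stroke-volume profile peaks in the cervical spine
and `Re` stays far below the laminar threshold — the flow regimes the
package is built to characterise.

One-call equivalents: `analyze_subject()` (objects in, `csf_subject` out)
and `run_subject(config.json, out)` (writes `profiles.csv`, `surface.csv`,
`summary.json`).  Cohort tools: `normalize_length()`, `cohort_stats()`,
`reliability_regression()`, `vertebral_lookup()`.  A thin CLI lives in
`exec/csfhydro` (`phantom`, `subject`, `reliability` subcommands).

## Tests

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "csfhydro", load_package = "installed")'
```

262 tests (unit, property-based and acceptance) run in ~25 s.  The
acceptance tests pin the package to its oracles: rasterised annuli within
2% of circle closed forms, sinusoid stroke-volume/amplitude closed forms
within 0.5%, hand-computed `Re`/`α`, end-to-end PWV recovery within 10% at
5% noise (20 replicates), stroke-volume peak localisation within ±3 mm,
and whole-spine total identities.

## Further reading

The methods vignette (`vignettes/csfhydro-methods.Rmd`) documents the
estimator choices — anti-aliased marching-squares perimeters, the cyclic
tensor-product smoothing spline behind `Q(z, t)`, why PWV is fitted at the
acquired slice locations, quadrature and slice-spacing resolution limits —
and the phantom's design and realism limits.
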