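Package: csfhydro
Title: Intrathecal Cerebrospinal Fluid Geometry and Hydrodynamics from MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies spinal intrathecal cerebrospinal-fluid (CSF) geometry
    and hydrodynamics from segmented anatomic MRI and phase-contrast MRI
    velocity exports.  Computes axial profiles of cross-sectional areas,
    wetted perimeters and hydraulic diameter from label volumes; converts
    per-pixel velocity series into offset-corrected volumetric flow
    waveforms; fuses per-slice waveforms into a smooth spatio-temporal flow
    surface to estimate pulse wave velocity; derives per-level stroke
    volume, peak flow rates, mean velocities, Reynolds and Womersley
    numbers; and summarises cohorts, including length normalisation,
    vertebral-level lookup and baseline versus follow-up reliability
    regression.  Ships a digital-phantom generator (annular geometry plus
    travelling-wave velocity exports with analytic ground truth) so the
    whole pipeline is testable without scanner data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    RNifti,
    jsonlite,
    mgcv
Suggests:
    readxl,
    optparse,
    knitr,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
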