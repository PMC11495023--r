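Package: csfflow
Title: Cardiac-Gated Phase-Contrast MRI Quantification of CSF Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies cerebrospinal fluid (CSF) flow from cardiac-gated
    phase-contrast MRI (PC-MRI). Converts stored phase-image pixel values to
    velocities using the velocity-encoding limit (VENC), estimates and
    subtracts the static baseline phase bias from a reference region of
    interest, corrects velocity aliasing by temporal phase unwrapping,
    integrates volumetric flow over the cardiac cycle (periodic trapezoid),
    and derives stroke volume, directional (antegrade/retrograde) volumes,
    net flow per cycle/minute/day, and flow-direction labels at the Sylvian
    aqueduct and cranio-cervical junction. Includes a synthetic acquisition
    simulator with exact ground truth for end-to-end validation, and cohort
    reporting utilities (direction counts, subgroup summaries, flow-volume
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
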