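Package: octmp
Title: Topographic Structure-Function Analysis of OCT Biomarkers and Microperimetry
Version: 0.1.0
Authors@R:
    person("OPTIMA", "Tools", email = "octmp@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for topographic structure/function
    studies in intermediate age-related macular degeneration. Generates synthetic
    eyes with en-face OCT biomarker maps (ellipsoid zone and outer nuclear layer
    thickness, drusen, subretinal drusenoid deposits, hyperreflective foci),
    fundus image pairs sharing a vessel tree, and 4-2 staircase microperimetry
    exams on a 45-point grid for two devices (MP-3, MAIA). Co-registers stimulus
    coordinates onto OCT en-face space via vessel segmentation, junction
    detection and least-squares similarity estimation, quantifies biomarkers
    within a 70 micrometre radius of each stimulus, and fits linear mixed-effects
    structure/function models with BIC-based model selection, eccentricity-slope
    linear combinations and marginal R-squared (GLMM).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
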