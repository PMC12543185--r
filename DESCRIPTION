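Package: lamsal
Title: Laminar VASO fMRI Analysis of Visual Saliency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for laminar cerebral-blood-volume
    (VASO) fMRI studies of visual saliency. Generates synthetic paired
    nulled/not-nulled acquisitions with known laminar ground truth, performs
    BOLD correction (BOCO), percent-signal-change scaling and block-design GLM
    fitting, unmixes partial-volume layer signals by spatial regression,
    computes normalized laminar saliency statistics, estimates layer-dependent
    effective connectivity with deconvolution-free generalized
    psychophysiological interaction (gPPI) models, back-projects depth-resolved
    responses into visual-field maps through corrected population receptive
    fields, simulates and fits 3-down-1-up staircase psychophysics with Weibull
    psychometric functions, and provides group inference: repeated-measures
    ANOVA with Greenhouse-Geisser correction, max-statistic permutation
    family-wise error control, Holm adjustment, and bivariate contour ellipse
    area (BCEA) fixation-stability metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    car,
    readxl
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
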