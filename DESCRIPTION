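Package: purescore
Title: Light-Corrected Pupillary Light Reflex Parameters and the Pupil
    Reactivity (PuRe) Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for smartphone pupillometry analysis. Fits a canonical
    double-sigmoid waveform to pupillogram traces, extracts the standard
    pupillary light reflex parameters (baseline, minimum and final diameter,
    constriction amplitude, constriction and dilation velocities, latency and
    recovery time), corrects each parameter for ambient lighting using
    per-parameter regression models selected by stepwise BIC search and
    LASSO fine-tuning, and combines the corrected parameters into the Pupil
    Reactivity (PuRe) score with its piecewise 0-5 clinical rescaling. A
    built-in synthetic cohort simulator with subject-level random effects,
    lighting-dependent baselines and a pharmacological mydriasis state makes
    the full pipeline testable end to end without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    glmnet
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
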