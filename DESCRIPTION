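Package: dietdx
Title: Frequency-Decomposition Diagnostics for Vibration-Based Breast Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tumor screening from actuated breast-surface motion in the
    style of Digital Image Elasto Tomography (DIET). Extracts a per-point spectral
    "frequency of interest" from forced-vibration displacement time series, reduces
    the surface to a 4 x 4 radial/vertical segment grid, applies a control-segment
    percentage-tolerance classifier swept over twelve control configurations, and
    evaluates performance with a bootstrapped ROC summarised by a one-parameter
    exponential curve fitted by total least squares. Includes a synthetic
    surface-vibration phantom with stiffness-dependent secondary tones for
    end-to-end testing when clinical recordings are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
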