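Package: curvecomp
Title: Fitting, Selecting, and Comparing Biologically Relevant Response
    Curves in Serial Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a cascade of biologically relevant response-curve models
    (flat, linear, sigmoid, double sigmoid, generalized double sigmoid) to
    serial gene expression measurements, using held-out evaluation points and
    the Relative Prediction Error (RPE) to select the most parsimonious curve
    that fits well. Classifies fitted curves into a shape taxonomy (flat,
    line, transition, hockey stick, sigmoid, impulse, step, impulse+, step+,
    each trending up or down), and compares the reported curves of one gene
    under two scenarios (species, drugs, stimuli) in terms of heteromorphy
    (different shapes), heterochrony (shifted transition times, HC) and
    heterometry (shifted magnitudes, HM). Includes a synthetic two-scenario
    data generator with planted curve families and planted HC/HM shifts,
    cross-tabulation reports, per-gene diagnostic plots, and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
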