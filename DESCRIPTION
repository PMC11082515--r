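Package: heartwoodkit
Title: Heartwood Onset, Dynamics and Drivers from Stem-Disc Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing heartwood formation in trees from stem-disc
    measurements. Computes derived xylem and foliar traits (hydraulically
    weighted vessel diameter, quadratic-mean radii, sapwood quantities, total
    conductive vessel area, anatomical maximum stomatal conductance),
    estimates size and age thresholds of heartwood onset as inflection points
    of logistic occurrence models, selects among candidate heartwood-dynamics
    models (linear, quadratic, power, three-parameter asymptotic exponential)
    by residual standard error, fits standardized major axis (SMA) allometries
    with common-slope tests and conduit-tapering indices, and decomposes age
    versus hydraulic drivers of heartwood area with recursive path models
    (direct, indirect and total standardized effects with Wald contrasts).
    Includes a seeded generator of two-cohort (shaded versus sun-exposed)
    tree datasets mirroring a real sampling design, and a pipeline that runs
    the full analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
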