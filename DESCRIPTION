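Package: nspef
Title: Cell-Size-Dependent Electroporation Thresholds and Membrane
    Resealing Kinetics for Nanosecond Pulsed Electric Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for nanosecond pulsed electric field
    (nsPEF) experiments on urothelial cells. Implements the charging-corrected
    steady-state Schwan model of the induced transmembrane potential, yielding
    electroporation-threshold electric fields as a function of cell radius and
    pulse duration; an analytic two-wire electrode field model for assigning
    exposure intensities to imaging sub-regions; single-exponential membrane
    resealing (dye-uptake) kinetics with amplitude-profiled least squares;
    spheroid swelling quantification; Hertz-model Young's modulus extraction
    from AFM force curves with post-exposure stiffness-decay fitting; cell
    morphometrics (form factor, H-score, weighted tissue-microarray
    summaries); Welch's one-way ANOVA with Dunnett's T3 post hoc test; and a
    calibrated synthetic-data generator that emulates every raw input so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
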