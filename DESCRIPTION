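Package: TasteCa
Title: Quantification of Taste-Evoked Calcium Responses and Two-Bottle
    Preference Tests
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing ratiometric (fura-2) calcium imaging of
    isolated taste receptor cells and two-bottle preference tests. Implements
    baseline estimation and 2-SD response detection on F340/F380 ratio traces,
    percent-over-baseline amplitude, onset/offset localisation with a
    return-to-baseline criterion, trapezoidal area-under-curve integration,
    KCl-based gating of presumptive Type III cells for umami analysis,
    responder-frequency chi-square tests, one-way ANOVA with Bonferroni
    post-hoc comparisons, and repeated-measures analysis of preference
    ratios over concentration series. A seeded synthetic-data generator
    produces fura-2-like traces and intake records with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    jsonlite
biocViews: CellBiology, Software, TimeCourse, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TasteCa-package.R'
    'TasteTraceSet.R'
    'io.R'
    'pipeline.R'
    'preference.R'
    'presets.R'
    'quantify.R'
    'simulate.R'
    'stats.R'
    'typing.R'
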