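Package: starchsugar
Title: Starch and Sugar Composition Database Construction and Dietary Intake Estimation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building a comprehensive starch and saccharide
    food-composition database from a partially analysed national food
    table by a stepwise value-assignment cascade (analytical values,
    literature aggregation, dry-weight scaling from the same or similar
    foods, recipe calculation, conversion from overseas tables), for
    classifying total sugar into free and naturally occurring sugar
    under the WHO definition via an ordered rule tree, and for
    estimating population intakes from multi-day weighed dietary
    records: absolute and energy-adjusted intakes, EI/EER screening,
    WHO free-sugar adherence, food-group source contributions, and
    habitual (usual) intake distributions by a best-power transform
    with one-way random-effects variance decomposition and shrinkage.
    Includes a synthetic-data generator with known ground truth so the
    whole pipeline is testable without access to restricted survey
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
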