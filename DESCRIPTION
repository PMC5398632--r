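Package: ttgrae
Title: Travelling-Gaussian Modelling of the Relative Age Effect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the relative age effect (RAE) in age-banded cohorts with
    a travelling-Gaussian threshold-selection model: a quality is N(A*t, 1)
    at birthtime t in [0,1], so selection above a criterion C compares
    Gaussian upper tails.  Estimates the annual advancement rate A and
    selection severity C from grouped birth-interval data (ordinal rating
    tables or selection counts against population pools) by probit
    transformation and ordinary least squares, including nested-model
    F tests for non-linearity.  Computes discrimination and wastage metrics
    (the discrimination index, wastage fraction, population expansion and
    contraction factors, mean selected birthtime), simulates cohorts from
    the forward model, and evaluates policy what-ifs such as criterion
    relaxation and cohort splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
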