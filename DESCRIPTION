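Package: rheoscan
Title: Rheostat, Toggle and Neutral Classification for Site-Saturation
    Mutagenesis Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of site-saturation substitution scans of
    membrane transporters and other proteins. Normalizes cellular uptake and
    cell-surface expression to wild type with per-batch background
    subtraction, computes expression-corrected transport with first-order
    error propagation, applies the undetectable-expression exclusion filter,
    classifies positions as rheostat, moderate rheostat, toggle or neutral
    with histogram-based RheoScale scores, and correlates substitution
    outcomes with amino-acid property scales, substrate identity,
    evolutionary conservation and variant-effect predictor bands. Includes a
    seeded synthetic-scan generator with known ground-truth archetypes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
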