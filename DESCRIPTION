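Package: dietmb
Title: Presence-Absence Diet Analysis from DNA Metabarcoding Read Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for downstream analysis of dietary DNA-metabarcoding data:
    cleaning of denoised ZOTU-by-sample read-count tables (per-sample and
    per-ZOTU proportional thresholds, blank/negative-control maximum
    subtraction, taxon aggregation, conversion to presence-absence),
    frequency-of-occurrence and origin-status summaries with nonparametric
    group comparisons, Hill diversity with coverage-based rarefaction and
    extrapolation and bootstrap confidence intervals, multivariate
    diet-composition analysis (Jaccard distances, NMDS, per-taxon binomial
    GLMs with resampling-based multivariate inference and AIC model
    selection), and seeded synthetic-data generators that emulate a fecal
    metabarcoding study of an omnivorous island reptile so every stage can
    be exercised without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
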