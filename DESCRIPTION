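Package: fgrs
Type: Package
Title: Family Genetic Risk Scores from Registry-Style Pedigree Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes family genetic risk scores (FGRS): per-person aggregate
    genetic-risk estimates built from the phenotypes of 1st- to 5th-degree
    relatives under a liability-threshold model. Binary diagnoses are converted
    to liability-scale z-scores from product-limit morbid risks, weighted by
    kinship, corrected for shared-household (cohabitation) effects estimated
    from not-lived-with fathers and from half-siblings reared together versus
    apart, shrunken with an empirical-Bayes reliability factor, and
    standardized by year of birth. Includes disorder-profile analyses
    (group means, ranking, specificity criteria, diagnostic hierarchies) and a
    synthetic registry simulator with known generative truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14.0),
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
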