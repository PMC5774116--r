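Package: pilblind
Title: Placebo Disclosure in Consent Leaflets, Blinding Indices, and
    Disclosure-Stratified Meta-Analysis
Version: 0.1.0
Authors@R:
    person("pilblind", "authors", email = "pilblind@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the wording of participant information
    leaflets (PILs) about a placebo control relates to blinding success and
    trial outcomes in randomized placebo-controlled trials. Provides
    rule-based coding of PIL text into full-disclosure, deceptive-disclosure
    and missing-information categories; Bang's blinding index per arm with
    Wald confidence intervals and the nine-scenario blinding classification;
    standardized mean differences (Hedges' g, and the logistic
    odds-ratio-to-SMD conversion) with shared-arm splitting for multi-arm
    trials; DerSimonian-Laird random-effects pooling under generic inverse
    variance with Cochran's Q / Higgins' I-squared subgroup comparison; a
    seeded synthetic trial-corpus generator calibrated to published summary
    statistics; and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
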