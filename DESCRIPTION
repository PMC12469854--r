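Package: senosynergy
Title: Senolytic Drug-Combination Synergy Prediction from Aging Genomics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assembling an aging-related target-gene universe from
    differential-expression contrasts and curated senescence gene databases,
    over-representation analysis of aging gene sets, construction of fused
    drug-pair and cell-line features over the gene universe, an attention-based
    neural regressor for drug-combination synergy scores, enumeration and
    ranking of candidate senolytic combinations, and post-processing of
    molecular-docking mode tables. Includes seeded synthetic-data generators
    emulating every input class so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
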