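Package: ontotrans
Title: Quality Control and Release Tooling for Multilingual Ontology Text
Version: 0.1.0
Authors@R:
    person("Ontotrans", "Developers", email = "ontotrans@example.org",
           role = c("aut", "cre"))
Description: Tools for maintaining professional translations of ontology
    text (labels, synonyms, definitions, comments). Implements a
    penalized, transformation-based bilingual similarity score that
    compares a professional translation against machine forward- and
    back-translations, classifies each translation as exact, passed or
    pending against a calibrated cutoff, and manages the sorted TSV
    translation ledger used to reconcile translated records with the
    current ontology text, emit task subsets, and produce release
    template tables. Includes penalty/cutoff calibration by grid search
    with an asymmetric preference against false positives, and a
    seeded synthetic bilingual corpus generator for end-to-end testing
    without any external translation service.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stringi,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
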