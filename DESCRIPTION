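Package: milancost
Title: Decision-Analytic Cost Model for Salivary Gland FNAC Under the Milan System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree and Monte Carlo cohort modeling of the cost of
    diagnosing salivary gland lesions by fine-needle aspiration cytology (FNAC)
    reported under the Milan System for Reporting Salivary Gland Cytopathology
    (MSRSGC), compared with upfront surgery. Ships US (CPT/Medicare) and German
    (DRG/OPS, EBM) tariff tables, MSRSGC-estimate and real-world Milan category
    distributions with per-category risk of malignancy, generic decision-tree
    evaluators (recursive roll-back and exhaustive path enumeration), a seeded
    patient-level Monte Carlo simulator, a synthetic cohort generator with
    parameter-recovery diagnostics, and scenario reporting across category-IVa
    management policies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
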