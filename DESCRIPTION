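Package: ahtnclass
Title: Antihypertensive Medication Classification for EHR Prescribing Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds, compares, and applies antihypertensive drug
    classification maps for electronic health record prescribing data in
    PCORnet-style common data model extracts. Classification maps are keyed
    either by raw medication name (first-word ingredient extraction with
    underscore-joined combination products) or by RxNorm concept unique
    identifier (RxCUI), and can be constructed from terminology relationship
    exports: ATC class membership, MED-RT may_treat/has_MoA relations, and
    Drug Ontology indication and mechanism-of-action RxCUI lists. Includes
    map reconciliation with audit trails, dose-form and indication screening
    (ophthalmic/topical products, BPH-indicated alpha-blockers), pairwise
    map comparison with difference categorization, hypertension cohort
    selection from diagnosis codes, per-class prescribing frequency tables,
    and a fully reproducible synthetic-data generator with ground-truth
    labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
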