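Package: synoptex
Title: Ontology-Constrained Structured Data Extraction from Breast Cancer
    Synoptic Pathology Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An agent-style pipeline for turning the free text of breast
    cancer synoptic pathology reports into structured, ontology-normalized
    records. Ships a normalized CAP-derived reporting ontology (8 sections,
    86 subsections, 229 fields), schema-driven report segmentation,
    deterministic prompt construction, a pluggable extraction-backend
    interface with a rule-based oracle matcher and seeded error injection,
    a synthetic validation-corpus generator with known ground truth, and a
    dual-regime evaluation engine (complete-truth metrics and positive-only
    recall) including reality-gap comparisons between synthetic and
    real-world performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glue,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
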