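Package: hafes
Title: Rule-Based Expert System for Hearing Aid Fitting from Patient Complaints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, explainable clinical decision-support engine that turns
    structured, numerically encoded patient complaints about hearing aids into
    prioritized, constraint-respecting fitting recommendations. Provides a
    validated knowledge-base format (fitting guide, electroacoustic parameter
    specifications, per-device constraint overrides, adjustment policy), a
    bilingual (English/French) six-question self-assessment questionnaire with
    numeric encoding and logical-consistency screening, a most-specific-match
    inference engine with explanation traces, a four-phase session workflow
    with audiologist review and satisfaction feedback, a seeded synthetic
    complaint generator, an optional Turtle ontology export, and a command-line
    interface. Ships a complete fixture for the Balafon hearing aid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
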