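Package: neuromcbs
Title: Clinical Benefit Scoring for Neuro-Oncology Therapies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rule-based grading of the magnitude of clinical benefit of
    neuro-oncology therapies from structured study-outcome records. Implements
    the Neuro-Oncology Magnitude of Clinical Benefit Scale (Neuro-MCBS) for
    single-arm studies and individual (n-of-1) patients, the ESMO-MCBS v1.1
    forms 2a, 2b, 2c and 3 with form routing and assessability rules, and the
    ASCO Net Health Benefit v2 value framework. Scales are shipped as
    declarative, versioned grade tables evaluated by a generic
    highest-grade-fulfilled engine with full audit trails; includes CSV/JSON
    record input and output, cohort-level benefit summaries, packaged study
    fixtures and a seeded synthetic patient-cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
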