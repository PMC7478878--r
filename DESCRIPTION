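Package: hfsms
Title: Rule-Based SMS Telemonitoring Engine for Heart-Failure Follow-Up
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline rule engine for short-message-service (SMS)
    telemonitoring of patients recently discharged after acute decompensated
    heart failure. Implements the message catalogs (feedback questions and
    unidirectional educational reinforcements), a day-granular outbound
    scheduler, a tolerant reply parser (yes/no tokens in English and
    Portuguese, locale-aware weight values), a five-rule alarm engine with
    once-per-streak debounce (non-response, nocturnal dyspnea, weight gain,
    missed medication, worsening fatigue), a seeded cohort simulator, and a
    reporting pipeline with a command-line front end. Ships a synthetic
    reconstruction of a published 10-patient prototype cohort for end-to-end
    replay.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
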