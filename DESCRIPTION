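Package: txtpro
Title: Two-Way Text-Message Patient-Reported Outcome Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A template-based engine for collecting patient-reported outcomes
    over two-way text messaging. Provides a declarative grammar for structured
    SMS self-reports (multi-site pain scores, school attendance codes,
    multi-item questionnaires), per-patient reporting schedules with completion
    windows and reminders, a conversation state machine with error-proofing
    replies and threshold-based clinical alarms, message pools that avoid
    repetitive prompts, compliance and validity statistics over the message
    log, and a synthetic-cohort simulator that exercises the whole pipeline
    without an SMS gateway.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
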