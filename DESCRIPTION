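Package: prognograde
Title: Adapted GRADE Quality-of-Evidence Grading for Prognostic Factor Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, auditable implementation of the GRADE framework
    as adapted for bodies of evidence about prognostic factors. Provides domain
    types for per-study evidence (phase of investigation, QUIPS risk-of-bias
    domain ratings, effect estimates with confidence intervals, indirectness
    flags, exposure-level series), inverse-variance fixed- and random-effects
    (DerSimonian-Laird) pooling with Cochran's Q and I-squared heterogeneity
    diagnostics, one rule-based assessor per GRADE factor (phase of
    investigation, study limitations, inconsistency, indirectness, imprecision,
    publication bias, moderate-or-large effect size, exposure-response
    gradient), a grading engine that combines the starting level with every
    factor adjustment into a four-point quality grade with a complete audit
    ledger, readers and writers for body-of-evidence documents (JSON, YAML,
    per-study CSV), summary-of-findings table output in meta-analysis and
    narrative layouts (Markdown and CSV), a command-line interface, and a
    seeded synthetic-evidence generator with known ground truth for testing
    every rule without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
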