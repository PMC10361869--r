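Package: lumencheck
Title: Screening Central-Venous Catheter Lumens for Physico-Chemical Drug
    Incompatibilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for algorithm-based physico-chemical incompatibility
    analysis of intravenous drugs co-administered through central-venous
    catheter lumens. Provides an open multi-source compatibility knowledge
    base format with drug-name normalization, a configurable policy that
    resolves conflicting evidence from several compatibility sources into a
    single auditable verdict per drug pair, sweep-line detection of
    simultaneous same-lumen co-administration in patient medication charts,
    cohort-level aggregation of incompatible pair findings, a four-step
    avoidance recommender (sequential administration, lumen reassignment via
    constrained graph coloring, pausing a continuous infusion, escalation to
    catheters with more lumens), scoring of staff knowledge questionnaires
    with Likert summaries, and seeded synthetic generators for cohorts and
    survey responses so the whole pipeline is testable without access to
    proprietary compatibility databases or real patient charts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
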