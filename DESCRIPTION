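Package: rorscreen
Title: Case/Non-Case Disproportionality Screening for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on individual case
    safety report (ICSR) databases: a MedDRA-like term hierarchy with
    SOC/HLGT/HLT/PT levels and a renal high-level-term selection, a
    three-table ICSR data model with delimited-text I/O, deterministic
    duplicate collapsing, rule-based case selection with an exclusion audit
    trail, report-level 2x2 contingency tables with reporting odds ratios
    (ROR), log-scale Wald confidence intervals and
    signal-of-disproportionate-reporting (SDR) flagging, descriptive
    case-characteristics and time-to-onset summaries, and a synthetic
    spontaneous-report generator with injected drug-event associations of
    known strength for end-to-end validation and interval-coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
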