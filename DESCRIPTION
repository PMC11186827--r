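Package: hazrank
Title: Semi-Quantitative Prioritisation of Food Safety Hazards in
    Circular Food Systems
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a-priori ranking of chemical and microbiological
    food safety hazards when food supply chains are made circular
    (re-use of manure, side streams, local sourcing).  Evidence on
    occurrence, environmental persistence (DT50, days per log
    reduction), transfer (log K_OC) or bio-accumulation (BAF), and
    human-health severity (health-based guidance values, DALY per
    case) is scored on an ordinal low/medium/high scale with
    configurable thresholds; ordinal scores are combined through
    decision matrices into a presence score and a final priority.  A
    Monte-Carlo batch-mixing simulation compares contaminant
    exceedance between short (single-field) and conventional
    (mixed-field) supply chains, and a censored-lognormal pool
    generator synthesises field-level concentration data from
    published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
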