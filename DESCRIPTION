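Package: anchorscreen
Title: Analysis of Anchored Drug Combination Screens with Bliss-Based
    Synergy Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing anchored (2 x 7)
    high-throughput drug combination screens in cancer cell lines:
    plate-level quality control (coefficient of variation and Z-factor
    rules), anchor-capped two-parameter sigmoid dose-response fitting,
    Bliss-independence synergy scoring via potency (delta IC50) and
    efficacy (delta Emax) shifts, biomarker discovery by ANOVA with
    Glass-delta effect sizes and Benjamini-Hochberg control,
    hypergeometric enrichment, and protein-interaction network distance
    analysis between drug targets and biomarkers. A synthetic screen
    generator with planted ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
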