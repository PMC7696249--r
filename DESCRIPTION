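Package: crosskill
Title: Cross-Species Drug-Screen Analysis for Viability Plate Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cross-species high-throughput drug
    screens on cell-line panels: percent-killing normalization of raw
    plate luminescence, hit calling, Analysis-of-Means selection of top
    compounds, hierarchical clustering and dog-versus-human concordance
    of response profiles, roll-up of hits to annotated drug targets,
    four-parameter logistic dose-response and Bliss-excess synergy,
    xenograft tumor-growth two-way ANOVA, and Kaplan-Meier log-rank
    cutoff scanning by marker expression. Includes a synthetic-data
    generator that emulates the statistical structure of two-species
    viability screens with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    minpack.lm,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
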