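Package: qsarlm
Title: Linear QSAR Modelling with Genetic Descriptor Selection and
    Applicability Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for small-sample quantitative structure-activity
    relationship (QSAR) modelling of kinase inhibitors: IC50 to pIC50
    conversion, descriptor-table handling, genetic function algorithm
    (GFA) descriptor-subset selection under a Friedman lack-of-fit
    score, ordinary least squares model fitting with collinearity
    (VIF) diagnostics, internal (leave-one-out Q2), external and
    Y-randomization validation, a leverage-based applicability domain
    with Williams-plot export, and virtual screening of candidate
    compounds with reliability flags and Lipinski rule-of-five
    filtering.  A synthetic-data generator reproduces the statistical
    structure the workflow assumes (sparse linear signal in correlated
    descriptor blocks) so every stage is testable without proprietary
    descriptor data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
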