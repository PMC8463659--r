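Package: qpcrcens
Title: Censored qPCR Array Analysis with Information-Theoretic Dependency Search
Version: 0.1.0
Authors@R:
    person("qpcrcens", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Quality control, endogenous-control normalization and group
    comparison for censored qPCR (TaqMan-style) miRNA array data. Amplifications
    below the detection limit are treated as right-censored observations on the
    delta-Cq scale: differential expression uses the two-sample log-rank test,
    fold changes follow the 2^-ddCq relative-quantitation convention, and
    differential detection uses Fisher's exact test. Endogenous controls are
    selected by geNorm stability ranking with pairwise-variation stopping.
    A multivariable dependency engine discretizes expression and phenotypes
    and searches for pairwise (mutual information) and three-way (symmetric
    delta / interaction information) dependencies, aggregating evidence into
    composite scores with stringent distribution-based filtering. A seeded
    synthetic-data generator emulates the assay (detection censoring at the
    Cq ceiling, stable control probes, planted level, detection and synergy
    effects) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    survival,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
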