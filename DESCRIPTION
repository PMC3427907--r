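Package: graphMCT
Title: Graphical Multiple Comparison Procedures with Weighted
    Bonferroni, Parametric and Simes Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construct and evaluate graphical multiple test procedures
    for clinical-trial multiplicity control.  A directed weighted graph
    (initial hypothesis weights plus a transition matrix) defines a
    weighting strategy for the full closure of intersection hypotheses;
    the closure can then be tested with weighted Bonferroni tests
    (including the sequentially rejective shortcut), weighted parametric
    min-p tests that exploit fully or partially known correlations
    between the test statistics, or weighted Simes tests under positive
    regression dependence.  Includes consonance and exhaustiveness
    diagnostics, adjusted p-values, standard-procedure constructors
    (Holm, fixed sequence, fallback, truncated Holm gatekeeping),
    Monte-Carlo familywise-error-rate and power estimation, and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    mvtnorm,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
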