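Package: indirep
Title: Evolutionary Dynamics of Cooperation Under Indirect Reciprocity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing a three-strategy evolutionary game of
    indirect reciprocity in which unconditional cooperators, unconditional
    defectors, and discriminators (conditional players who copy their
    current partner's publicly observed previous-round action) are matched
    at random over N rounds. Provides closed-form expected payoffs
    cross-validated by round-by-round summation, replicator dynamics on the
    strategy simplex with tangent-plane fixed-point classification,
    interior and boundary equilibrium root-finding, a one-shot Nash
    classification, a finite-population agent-based Monte-Carlo oracle,
    and ternary phase-portrait plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: graphics, grDevices, jsonlite, stats, tools, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
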