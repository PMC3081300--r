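Package: natureindex
Title: Nature Index Computation for Biodiversity Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes composite biodiversity indexes of the Nature Index
    family. Expert-elicited indicator observations (mean with lower and
    upper quartiles) are turned into per-cell statistical distributions by
    least-squares matching of the expectation and both quartiles across a
    set of candidate families, Monte-Carlo replicates of the elicitation
    process are drawn, each replicate is scaled against an indicator- and
    locality-specific reference state, and scaled values are aggregated
    over indicators, major ecosystems, spatial units and dates under a
    hierarchical weighting scheme. Results are reported as medians with
    95% confidence intervals and simulation-based p-values, together with
    documentation-gap diagnostics. A synthetic-data generator emulating
    the expert data-entry process supports end-to-end testing with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
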