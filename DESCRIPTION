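Package: heterosisr
Title: Quantitative Expression Heterosis Analysis for Hybrid Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying nonadditive gene and protein expression
    in hybrids relative to their inbred parents. Implements per-run
    anchor-genotype normalization of multiplexed (TMT-style) abundance
    matrices and counts-per-million scaling, midparent/high-parent/low-parent
    contrast construction with Welch tests and Benjamini-Hochberg control,
    five-way nonadditivity classification, correlation of expression
    heterosis with trait heterosis (plant height) across a hybrid panel,
    hypergeometric set enrichment, mutant-versus-hybrid phenocopy
    concordance, and a fully seeded synthetic panel generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
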