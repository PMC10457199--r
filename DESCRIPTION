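Package: pqtlflow
Title: Protein Quantitative Trait Locus Meta-Analysis, Colocalization and
    Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for discovery and causal interpretation of
    protein quantitative trait loci (pQTLs) from cohort-level GWAS summary
    statistics: cohort quality control, fixed-effects inverse-variance
    meta-analysis with heterogeneity-aware significance filters, locus
    definition with sentinel variants and cis/trans classification,
    approximate stepwise conditional analysis from summary statistics and
    an LD reference, proportion of variance explained, Bayesian pairwise
    colocalization with a conditional-then-colocalize extension for
    multi-signal loci, cis Mendelian randomization of proteins on disease
    outcomes with correlated instruments and HEIDI outlier filtering, and
    candidate-mediator prioritization at trans loci. A synthetic-data
    generator produces multi-cohort summary statistics with known ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    IRanges,
    optparse
Config/testthat/edition: 3
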