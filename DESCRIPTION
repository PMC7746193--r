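Package: waldscan
Title: Domain Tolerability and Mutational Survivorship Bias Analysis for
    Multidomain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to ask whether the variants observed in a multidomain
    protein are subject to survivorship bias, i.e. whether one domain looks
    mutation-rich only because it tolerates damage. The package grades
    per-residue conservation from an ortholog multiple sequence alignment,
    builds a per-residue dN/dS mutational-tolerance landscape from
    population single-nucleotide variants corrected for codon composition,
    calls disease-propensity hotspots from a saturation-mutagenesis score
    matrix, compares domains with chi-squared, Kolmogorov-Smirnov,
    Mann-Whitney and ANOVA/Tukey tests, and combines the four lines of
    evidence into a "Wald's domain" verdict. A synthetic-data generator
    produces complete input bundles with known ground truth for
    calibration and parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'genetic-code.R'
    'core-model.R'
    'conservation.R'
    'tolerance.R'
    'hotspots.R'
    'compare.R'
    'pipeline.R'
    'simulate.R'
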