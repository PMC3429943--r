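Package: sibtrio
Title: Trio Sibship Likelihood Ratios from STR Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kinship testing toolkit for the trio sibship design, in which
    an individual is tested against two reference full siblings using
    autosomal short tandem repeat (STR) genotypes.  Computes per-locus and
    combined likelihood ratios (sibling index) for the full-sibling versus
    unrelated hypotheses by exact summation over parental genotype pairs,
    enumerates and verifies the closed-form likelihood-ratio formulas for
    all non-excluded trio genotype classes, simulates virtual sibling and
    non-sibling populations under Hardy-Weinberg equilibrium from allele
    frequency tables, and summarises classification performance
    (sensitivity, specificity, predictive values, accuracy) at chosen
    likelihood-ratio thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
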