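Package: chipsip
Title: Quantitative Analysis of Chip-SIP Stable Isotope Probing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of Chip-SIP experiments, in
    which rRNA from isotopically labeled microbial communities is hybridized
    to a phylogenetic microarray and probe spots are imaged by NanoSIMS.
    Converts per-spot secondary-ion counts into background-corrected permil
    enrichment, estimates per-OTU hybridization-corrected enrichment (HCE) as
    the regression slope of enrichment on fluorescence, calls isotopically
    enriched taxa with a dual slope/FDR criterion and a replicate consensus
    rule, tests treatment effects on incorporation by ANCOVA with a
    treatment-by-fluorescence interaction, and attributes community-level
    isotope incorporation to families by weighting mean HCE with 16S read
    abundance. Includes a seeded synthetic-data generator with Poisson ion
    counting and known ground truth, and specificity screening for
    oligonucleotide probe design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    Biostrings,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
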