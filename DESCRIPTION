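Package: rflpTyper
Title: In Silico PCR-RFLP Assay Design and Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs and executes in-silico PCR-RFLP (restriction fragment
    length polymorphism) species-identification assays. Scans grouped
    multiple sequence alignments for fixed diagnostic SNPs, predicts
    restriction-digest fragment patterns from degenerate (IUPAC)
    recognition sites, builds stepwise identification keys, and classifies
    unknown sequences or observed gel band patterns. Ships the six-enzyme
    mtORF/PocHistone assay panel that discriminates the six Hawaiian
    Pocillopora coral species, together with a constraint-satisfying
    synthetic haplotype generator so the whole pipeline is testable
    without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
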