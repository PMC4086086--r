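Package: cutdesign
Title: Design and Specificity Ranking of CRISPR/Cas9 and TALEN Genome-Editing Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline design engine for CRISPR/Cas9 single-guide RNAs and
    TALEN pairs against a locally supplied genome. Enumerates candidate target
    sites (20 bp protospacer + NGG PAM for Cas9; 5'-T anchored monomer pairs
    across a 14-20 bp spacer for TALENs), exhaustively searches the genome for
    off-target occurrences under several mismatch models using a k-mer seed
    index, and ranks candidates by off-target severity, GC content, a
    PAM-proximal guanine and 5' gene position. Also designs and
    specificity-ranks genotyping PCR primer pairs around the predicted cut
    site, maps restriction sites (including sites inside TALEN spacers), and
    writes TSV and GenBank reports. Includes a seeded synthetic-genome
    generator with planted on- and off-target structures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
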