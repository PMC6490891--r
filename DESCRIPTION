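Package: famscan
Title: Genome-Wide Gene-Family Characterization for ABC Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide characterization of the
    ATP-binding cassette (ABC) transporter gene family: identification of
    family members from domain-hit tables, domain-architecture topology
    classification (full/half/quarter-sized, forward/reverse, ABC2),
    subfamily assignment against a labeled reference set, neighbor-joining
    phylogenies with bootstrap support, Nei-Gojobori Ka/Ks estimation with
    selection-pressure classification and synonymous-clock duplication
    dating, promoter extraction with IUPAC degenerate cis-element scanning,
    and placental expression profiling via RPKM and the 2^-ddCt method.
    Includes seeded synthetic-data generators that emulate proteomes,
    diverged codon-sequence pairs, promoters with planted motifs, and read
    count matrices, so every stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
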