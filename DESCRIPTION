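Package: g4coloc
Title: G-Quadruplex Scanning and Breakpoint Colocalization Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@g4coloc.org",
           role = c("aut", "cre"))
Description: Detects putative G-quadruplex sequences (PQS) in genomic DNA
    on both strands and assigns each candidate an explicit integer
    stability score; extracts variant breakpoints from VCF small
    variants, BEDPE structural variants, and copy-number segment files;
    builds fixed-width windows around breakpoint ends; and tests
    window-to-G4 colocalization against a random-placement permutation
    null with empirical p-values. A synthetic-data generator produces
    genomes with planted G4 motifs and breakpoints placed with a tunable
    G4-proximity bias, so calibration and power of the permutation test
    can be measured without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    vcfR,
    methods,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
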