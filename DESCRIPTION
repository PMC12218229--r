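Package: amirna
Title: Engineering and Small RNA-Seq Analysis of Artificial miRNA Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based engineering of primary microRNA (pri-miRNA) hairpins
    into artificial miRNA (amiRNA) scaffolds carrying the sequence and
    structure determinants of efficient DROSHA/DICER processing (basal GU
    dinucleotide, CHC basal-stem bulge, miR-30a terminal loop, 35-bp stem,
    unstructured basal flanks), together with the companion small RNA-seq
    analysis: flank-extended per-scaffold reference windows, strict
    CIGAR-based read classification, guide/passenger strand quantification,
    and 5'/3' processing-precision profiles. Secondary-structure validation
    is delegated to an injected minimum-free-energy folding service (the
    ViennaRNA RNAfold command-line tool by default). A seeded read simulator
    with configurable cleavage-site jitter and strand bias makes the whole
    pipeline testable without sequencing data, and small calculators cover
    the flow-cytometry reporter normalization and 2D-ddPCR genome-integrity
    readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: ViennaRNA RNAfold (for the default folding service)
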