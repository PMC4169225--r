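Package: lampis
Title: Identification and Annotation of Viral Vector Integration Sites from
    LAM-PCR Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end processing of linear-amplification-mediated PCR
    (LAM-PCR) sequencing reads for gene-therapy integration-site (IS)
    monitoring: paired-end collapse, exact-barcode demultiplexing, long
    terminal repeat (LTR) and linker-cassette trimming, alignment of the
    genomic fragments against a reference genome carrying the vector as a
    dummy chromosome, ambiguity-aware read classification, 3-bp sliding-window
    merging of redundant sites into loci, and nearest-feature annotation from
    BED files.  Includes a seeded synthetic-data generator that plants
    integration sites with known coordinates so every stage can be validated
    against ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
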