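Package: gataslc
Title: Identification and Prioritization of GATA Factor-Regulated Solute
    Carrier Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for identifying solute carrier (SLC) transporter
    genes regulated by the erythroid transcription factors GATA1 and GATA2
    from replicate expression contrasts, partitioning them into
    factor-specific and co-regulated cohorts, testing substrate-class
    enrichment against the full transporter family, integrating ChIP-seq,
    ATAC-seq and candidate cis-regulatory element intervals to call
    predicted intronic enhancers, testing WGATAR and E-box motif enrichment
    with a matched-background permutation test, and ranking candidate
    genes by regulation magnitude and regulatory evidence. Includes a
    seeded synthetic-data generator that emulates the statistical structure
    of the underlying erythroid datasets so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
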