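Package: srnaprofiler
Title: Annotation and Profiling of Small RNA Sequencing Data with
    Emphasis on tRNA- and rRNA-Derived Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An annotation pipeline for small RNA sequencing data that
    collapses and filters reads, annotates unique sequences
    hierarchically against a genome and a series of non-coding RNA
    reference sets, classifies tRNA-derived small RNAs (tsRNAs) by
    their derivation locus (5' terminus, 3' terminus, 3' CCA end),
    profiles positional coverage of tsRNAs and rRNA-derived small RNAs
    (rsRNAs) along their precursors, and predicts candidate RNA
    modification sites from mismatch pileups with a binomial
    enrichment test.  Includes a deterministic synthetic-data
    generator producing toy genomes, reference bundles and reads with
    known ground truth, so the whole pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
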