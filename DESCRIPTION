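Package: duplexffpe
Title: Duplex Consensus Sequencing Analysis and FFPE Library Simulation
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Coordinate-keyed (UMI-free, bottleneck-style) duplex consensus
    sequencing analysis for formalin-fixed paraffin-embedded (FFPE) DNA:
    read-pair filtering, per-strand PCR-family consensus calling, duplex
    merging, population-SNP filtering and mutation-load estimation with
    exact binomial confidence intervals.  Includes a generative simulator
    of FFPE duplex libraries (single-strand lesions, 5'-overhangs,
    polymerase end-repair error copying versus nuclease blunting, strand
    dropout, bottleneck sampling and PCR duplication) so the whole
    pipeline is testable end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    Rsamtools,
    GenomicRanges,
    IRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
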