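Package: circshrna
Title: Junction-Spanning shRNA Design and Off-Target Verification for
    circRNA Knockdown
Version: 0.1.0
Authors@R:
    person("circshrna", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for specific knockdown of exonic circular RNAs
    (circRNAs) with short hairpin RNAs (shRNAs) directed against the
    back-splice junction, the only sequence that distinguishes the circle
    from the linear mRNA of the host gene. Provides strand-aware
    extraction of spliced, circular and 3' UTR sequences from genome
    FASTA plus GTF/BED annotation; design of 21-nt junction-spanning
    guides including a shifted alternate design; exhaustive scanning of a
    transcriptome for perfect complementary stretches above a length
    threshold; hypergeometric seed-word enrichment landscapes over ranked
    differential-expression lists; filtering and verdict rules for
    calling putative off-targets from differential-expression tables; and
    deterministic synthetic-data generators so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
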