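Package: varodds
Title: Likelihood-Based Re-Evaluation of Candidate Genome Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-scores candidate SNP and indel variants against aligned
    sequencing reads under an explicit generative model of the read data.
    Each candidate (or cluster of nearby candidates) is turned into explicit
    diploid genome hypotheses; the probability of every read is computed as a
    sum over read-length segments of each hypothesis haplotype, absorbing
    multi-mapping and local gap-placement ambiguity, with an integrated term
    for reads derived from paralogs absent from the reference. Variants are
    reported with marginal posterior odds suitable for ranking and
    precision-recall evaluation, and a bundled simulator generates diploid
    genomes, error-bearing reads, and decoy candidates for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    vcfR,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
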