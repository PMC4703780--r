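Package: chemoguild
Title: Genome-Centric Metagenomics and Chemostat Mass Balance for
    Denitrifying and Fermentative Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-centric analysis of anoxic enrichment
    communities that couple denitrification and fermentation.  Provides a
    synthetic community generator (genomes with population-specific
    tetranucleotide signatures, fragmentation into contigs, seeded DNA and
    RNA read simulation, chemostat and batch observations), tetranucleotide
    contig binning with GC/coverage blob diagnostics, read-mapping based
    abundance estimation for metagenome-assembled genomes, single-copy
    marker and tRNA completeness census, six-frame-translation profile
    scanning for the functional genes nirS, nirK, nosZ and pflB,
    length-normalized per-gene transcriptional activity, functional guild
    classification and aggregation, and chemostat stoichiometry (C:N
    ratios, nitrogen balance, protein prediction, growth yield, and batch
    rate estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
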