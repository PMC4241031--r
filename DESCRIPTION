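Package: enumap
Title: Mapping-by-Sequencing for ENU Mutagenesis Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate causal point mutations from whole-genome
    sequencing of a single affected mouse in an ENU (N-ethyl-N-nitrosourea)
    outcross pedigree. Provides a variant-filter cascade (blacklist
    subtraction, depth, allele balance, strand skew, homopolymer context,
    repeat masking and local variant clustering) with per-stage accounting,
    two-point LOD linkage mapping for a fully penetrant recessive trait in
    an intercross, hidden Markov model segmentation of the genome into
    diplotype-ancestry states from windowed homozygous/heterozygous variant
    densities, and consequence annotation that nominates homozygous
    protein-sense-affecting candidates inside founder-homozygous segments.
    A seeded simulator of the outcross pedigree (recombinant ancestry
    mosaics, strain-divergence SNPs, sparse ENU mutations, one planted
    recessive causal coding mutation, low-coverage genotyping noise and a
    polymorphic marker panel) exercises the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
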