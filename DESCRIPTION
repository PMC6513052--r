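Package: coipop
Title: Population Genetics and Barcoding Analysis of Mitochondrial COI Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for phylogeographic analysis of mitochondrial
    cytochrome c oxidase subunit 1 (COI) amplicon data: FASTA import with
    population metadata, trimming and translation-based quality control,
    haplotype collapsing, Nei haplotype and nucleotide diversity, Tajima's D
    and Fu's Fs neutrality tests with coalescent p-values, mismatch
    distribution analysis under the sudden-expansion model with parametric
    bootstrap goodness-of-fit, one-level and hierarchical AMOVA with
    permutation tests, pairwise Phi-ST matrices with Holm correction, Mantel
    tests of isolation by distance, minimum-spanning haplotype networks with
    haplogroup delineation, neighbor-joining barcoding with bootstrap support,
    and coalescent simulators (island model, sudden expansion, species panels)
    for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phangorn,
    ade4,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
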