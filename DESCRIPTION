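Package: lifecyclechromatin
Title: Chromatin Landscape Analysis Across a Haploid-Diploid Life Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of histone post-translational modification
    (PTM) ChIP-seq across the sporophyte and gametophyte generations of a
    haploid-diploid life cycle. Partitions a genome annotation into
    TSS-proximal, exonic, intronic and intergenic feature classes with a
    transposon overlay; calls enriched intervals from binned coverage with a
    Poisson background model; segments broad multi-gene domains and tests
    domain-border proximity to gene starts and ends against random genomic
    anchors; assigns 16 combinatorial chromatin states from four TSS-localised
    marks and summarises state transitions at generation-biased genes; and
    analyses divergent gene pairs, including shared nucleosome-depleted
    regions called from MNase coverage. A seeded synthetic-data generator
    produces toy genomes, expression matrices and coverage tracks with ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Encoding: UTF-8
Config/testthat/edition: 3
RoxygenNote: 7.3.3
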