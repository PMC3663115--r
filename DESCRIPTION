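Package: retrocall
Title: Detection of Gene Retrocopy Insertion Polymorphisms from Paired-End
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects gene retrocopy insertion polymorphisms (GRIPs) --
    retrotransposed, intron-less copies of spliced gene transcripts that are
    present in sequenced genomes but absent from the reference assembly --
    from coordinate-sorted paired-end alignments. Candidate insertions are
    found by clustering discordant read pairs that link exons of a source
    gene to a distal locus, refined with soft-clip breakpoints, target site
    duplications, poly-A tails and endonuclease cleavage motifs, and
    confirmed by local de Bruijn assembly of exon-exon junctions. Includes
    multi-sample pooling for low-pass cohorts, tumor/normal somatic
    subtraction, reference-retrocopy recovery from deletion calls, Jaccard
    profile distances with hierarchical clustering, Watterson/Tajima
    estimators of the retroposition rate, and a spike-in simulator for
    benchmarking precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
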