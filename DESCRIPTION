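Package: pentaspot
Title: Pentanucleotide Mutation Coldspot and Hotspot Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects 5-nucleotide DNA sequence motifs that are rarely
    (coldspots) or frequently (hotspots) associated with single-nucleotide
    mutations in disease genes. Gene sequences are assembled from exons with
    fixed-length intron flanks and 2-nt UTR padding, segmented into
    overlapping 5-nt windows, and collapsed with their reverse complements
    into 512 canonical motifs. Per-motif mutation tallies at window middle
    positions are tested against expected coldspot (25%) and hotspot (75%)
    mutation probabilities with one-sample proportion tests, combined across
    genes and strands by Fisher's method, and classified at a fixed
    significance threshold. Includes motif feature characterization (purine
    tracts, middle-position CpG, position frequency matrices, substitution
    spectra), held-out-gene class-association validation, and a synthetic
    mutation-landscape simulator with planted motif classes for power and
    recovery analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    VariantAnnotation,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Software, Genetics, SNP, SequenceMatching, StatisticalMethod
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'gene-model.R'
    'mutation-catalog.R'
    'motif-stats.R'
    'motif-features.R'
    'pentaspot-package.R'
    'validation.R'
    'simulate.R'
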