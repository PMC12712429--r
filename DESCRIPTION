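Package: drykit
Title: Sex-Chromosome Inference and Desiccation Time-Course Analysis for
    Resurrection-Plant Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the bespoke computations of resurrection-plant
    genome and transcriptome studies: canonical k-mer set algebra for
    inferring XY/ZW heterogamety from sexed cohorts and localizing the
    sex-determining region by window density; sliding-window gene and
    repeat coverage statistics with telomere detection; relative water
    content bookkeeping and differential-abundance summarization
    (thresholding, nonredundant lists, Venn overlaps, alluvial flows)
    across field dehydration-rehydration time courses; a Mapper
    topological-data-analysis graph over samples under a physiological
    lens; strand-aware promoter extraction with IUPAC cis-regulatory
    element scanning and binomial-GLM enrichment; and peptide
    charge-hydropathy descriptors for LEA and ELIP proteins. A seeded
    synthetic-data generator emulates every input so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
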